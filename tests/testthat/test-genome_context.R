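test_that("the 80/80 duplication caller reports planted pairs only", {
  g <- fix_genome()
  dup <- detect_duplications(g$cds, g$loci)
  # planted: one pair at 0.95/0.95 (reported), one at 0.70/0.90 (below)
  expect_equal(nrow(dup), 1)
  tr <- g$truth$dup_pairs[g$truth$dup_pairs$identity > 0.8, ]
  expect_equal(dup$gene_a, tr$gene_a)
  expect_equal(dup$gene_b, tr$gene_b)
  expect_equal(dup$type, "segmental")
  expect_equal(dup$coverage, tr$coverage, tolerance = 0.02)
  expect_equal(dup$similarity, tr$identity, tolerance = 0.02)
})

test_that("duplication decisions equal a brute-force alignment oracle", {
  g <- generate_family_genome(
    n_genes = 6, n_chromosomes = 3,
    dup_pairs = list(c(0.92, 0.90), c(0.84, 0.88), c(0.90, 0.60)),
    seed = 23)
  # shorten genes for the quadratic oracle
  cds <- g$cds
  cds$seq <- substr(cds$seq, 1, 240)
  called <- detect_duplications(cds, min_cov = 0.8, min_sim = 0.8)
  called_keys <- paste(called$gene_a, called$gene_b)
  oracle_keys <- character(0)
  for (i in 1:(nrow(cds) - 1)) {
    for (j in (i + 1):nrow(cds)) {
      o <- overlap_oracle(cds$seq[[i]], cds$seq[[j]])
      if (o$coverage > 0.8 && o$similarity > 0.8) {
        oracle_keys <- c(oracle_keys, paste(sort(c(cds$id[[i]], cds$id[[j]])),
                                            collapse = " "))
      }
    }
  }
  expect_setequal(called_keys, sort(oracle_keys))
})

test_that("spliced alignment recovers planted exon structures exactly", {
  g <- fix_genome()
  for (gid in g$loci$gene_id) {
    chr <- g$loci$chromosome[g$loci$gene_id == gid]
    mod <- spliced_align(g$cds$seq[g$cds$id == gid],
                         g$genome$seq[g$genome$chromosome == chr], gid)
    tr <- g$truth$exons[g$truth$exons$gene_id == gid, ]
    expect_equal(nrow(mod), nrow(tr), info = gid)
    expect_equal(mod$start, tr$start, info = gid)
    expect_equal(mod$end, tr$end, info = gid)
    expect_equal(mod$strand[[1]], tr$strand[[1]], info = gid)
    expect_true(all(mod$gt_ag), info = gid)
    # intron count = exon count - 1, introns all >= 1 bp
    intr <- model_introns(mod)
    expect_equal(nrow(intr), nrow(mod) - 1L)
    expect_true(all(intr$length >= 1))
  }
})

test_that("an intronless CDS maps to a single exon", {
  set.seed(9)
  cds <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  genomic <- paste0(paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                          collapse = ""), cds,
                    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                          collapse = ""))
  mod <- spliced_align(cds, genomic)
  expect_equal(nrow(mod), 1)
  expect_equal(mod$start, 501L)
  expect_equal(mod$end, 800L)
  expect_error(spliced_align(strrep("ACGT", 50), genomic), "structure-not-found")
})

test_that("intron-count histograms summarize gene models", {
  t3 <- gh_table3()
  models <- purrr::map_dfr(seq_len(nrow(t3)), function(i) {
    n_ex <- if (is.na(t3$exon3_start[[i]])) 2L else 3L
    tibble::tibble(gene_id = t3$gene[[i]], exon = seq_len(n_ex))
  })
  h <- summarize_intron_counts(models)
  expect_equal(h$n_genes[h$n_introns == 1], 38L)
  expect_equal(h$n_genes[h$n_introns == 2], 2L)
  expect_equal(nrow(summarize_intron_counts(models[0, ])), 0)
})

test_that("exon arithmetic reproduces printed protein lengths where consistent", {
  t3 <- gh_table3()
  expect_len <- function(gene, aa) {
    r <- t3[t3$gene == gene, ]
    lens <- c(r$exon1_end - r$exon1_start + 1, r$exon2_end - r$exon2_start + 1,
              if (!is.na(r$exon3_start)) r$exon3_end - r$exon3_start + 1)
    chk <- check_length_consistency(lens, aa)
    expect_equal(chk$implied_length, aa, info = gene)
    expect_true(chk$pass, info = gene)
  }
  expect_len("GhHsf7", 515)
  expect_len("GhHsf39", 380)
  expect_len("GhHsf2", 332)
})

test_that("known table inconsistencies land in the discrepancy report", {
  rep <- check_table_consistency()
  linker <- rep[rep$check == "linker_vs_coordinates", ]
  expect_true("GhHsf4" %in% linker$gene)
  expect_equal(linker$observed[linker$gene == "GhHsf4"], 26)
  dbd <- rep[rep$check == "dbd_length_vs_text", ]
  expect_setequal(dbd$gene, c("GhHsf24", "GhHsf29", "GhHsf30", "GhHsf33"))
  len <- rep[rep$check == "implied_protein_length", ]
  expect_true(all(c("GhHsf22", "GhHsf40") %in% len$gene))
  # 37 of 40 cross-table rows are consistent
  expect_equal(nrow(len), 3)
})

test_that("tandem clusters require adjacency on one chromosome", {
  g <- fix_genome()
  cl <- find_tandem_clusters(g$loci)
  expect_equal(sort(unique(cl$size)), 3L)
  expect_setequal(cl$gene_id, g$truth$tandem)

  # genes on different chromosomes never cluster
  loci <- tibble::tibble(gene_id = c("a", "b"), chromosome = c("chr1", "chr2"),
                         start = c(1L, 1L), end = c(100L, 100L))
  expect_equal(nrow(find_tandem_clusters(loci)), 0)

  # census-based window: 2+2 planted clusters come out as two clusters
  census <- tibble::tibble(
    gene_id = paste0("g", 1:40), chromosome = "chr1",
    start = seq(1000L, by = 10000L, length.out = 40))
  fam <- census[c(3, 4, 25, 27), ]
  fam$end <- fam$start + 500L
  cl2 <- find_tandem_clusters(fam, window = 5, gene_census = census)
  expect_equal(nrow(cl2), 4)
  expect_equal(sort(unique(cl2$cluster)), 1:2)
  expect_equal(unname(table(cl2$cluster)), c(2L, 2L), ignore_attr = TRUE)
})
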