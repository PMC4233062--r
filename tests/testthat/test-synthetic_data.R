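test_that("planted proteins carry the class-defining insertions and linkers", {
  for (cls in c("A", "B", "C")) {
    for (s in 1:5) {
      res <- generate_hsf_protein(cls, seed = s)
      expect_equal(res$truth$insertion,
                   c(A = 21L, B = 0L, C = 7L)[[cls]],
                   ignore_attr = TRUE)
      lr <- list(A = c(12, 37), B = c(16, 77), C = c(10, 29))[[cls]]
      lk <- res$truth$linker_length
      expect_true(lk >= lr[1] && lk <= lr[2])
      # linker convention: HR-A start - DBD end
      expect_equal(res$truth$hra_start - res$truth$dbd_end, lk)
      # planted insertion equals residues strictly between the heptad cores
      expect_equal(res$truth$hrb_start - res$truth$hra_end - 1L,
                   res$truth$insertion)
    }
  }
})

test_that("generators are deterministic in the seed", {
  a <- generate_hsf_protein("A", seed = 3)
  b <- generate_hsf_protein("A", seed = 3)
  expect_identical(a, b)
  g1 <- generate_family_genome(n_genes = 4, n_chromosomes = 2, seed = 5)
  g2 <- generate_family_genome(n_genes = 4, n_chromosomes = 2, seed = 5)
  expect_identical(g1, g2)
  e1 <- generate_ests(g1$cds$seq[[1]], coverage = 3, read_len = 80, seed = 2)
  e2 <- generate_ests(g1$cds$seq[[1]], coverage = 3, read_len = 80, seed = 2)
  expect_identical(e1, e2)
  c1 <- generate_ct_table(default_heat_patterns()[1:4, ], seed = 8)
  c2 <- generate_ct_table(default_heat_patterns()[1:4, ], seed = 8)
  expect_identical(c1, c2)
})

test_that("family genomes plant duplications, tandem clusters and GT-AG introns", {
  g <- fix_genome()
  expect_equal(nrow(g$truth$dup_pairs), 2)
  expect_true(all(g$truth$dup_pairs$gene_a %in% g$loci$gene_id))
  expect_true(all(g$truth$dup_pairs$gene_b %in% g$loci$gene_id))
  # duplicate partners always on different chromosomes (segmental planting)
  for (k in seq_len(nrow(g$truth$dup_pairs))) {
    ca <- g$loci$chromosome[g$loci$gene_id == g$truth$dup_pairs$gene_a[[k]]]
    cb <- g$loci$chromosome[g$loci$gene_id == g$truth$dup_pairs$gene_b[[k]]]
    expect_false(ca == cb)
  }
  # tandem cluster genes share a chromosome and adjacent ranks
  tand <- g$loci[g$loci$gene_id %in% g$truth$tandem, ]
  expect_equal(length(unique(tand$chromosome)), 1)
  expect_equal(nrow(tand), 3)
  # every intron starts GT and ends AG in transcript orientation
  for (gid in g$loci$gene_id) {
    ex <- g$truth$exons[g$truth$exons$gene_id == gid, ]
    if (nrow(ex) < 2) next
    chr <- g$genome$seq[g$genome$chromosome ==
                          g$loci$chromosome[g$loci$gene_id == gid]]
    strand <- ex$strand[[1]]
    ex <- ex[order(ex$start), ]
    for (i in seq_len(nrow(ex) - 1)) {
      intron <- substr(chr, ex$end[[i]] + 1L, ex$start[[i + 1L]] - 1L)
      if (strand == "-") intron <- rc_str(intron)
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
  expect_error(generate_family_genome(n_genes = 1, dup_pairs = list(c(.9, .9))),
               "n_genes")
  expect_error(generate_family_genome(n_genes = 4, dup_pairs = list(c(1.2, .9))),
               "identity and coverage")
})

test_that("EST reads are error-free substrings at error 0 and empty at coverage 0", {
  g <- fix_genome()
  cds <- g$cds$seq[[3]]
  reads <- generate_ests(cds, coverage = 4, read_len = 90, error_rate = 0, seed = 6)
  expect_true(all(c("+", "-") %in% reads$strand))
  for (i in seq_len(nrow(reads))) {
    r <- if (reads$strand[[i]] == "-") rc_str(reads$seq[[i]]) else reads$seq[[i]]
    expect_true(grepl(r, cds, fixed = TRUE))
  }
  expect_equal(nrow(generate_ests(cds, coverage = 0, read_len = 90, seed = 1)), 0)
  expect_error(generate_ests(cds, coverage = 2, read_len = nchar(cds) + 1),
               "read_len")
})

test_that("EST substitution errors match the requested rate (binomial check)", {
  g <- fix_genome()
  cds <- g$cds$seq[[1]]
  rate <- 0.01
  read_len <- 100
  reads <- generate_ests(cds, coverage = round(10000 / nchar(cds)),
                         read_len = read_len, error_rate = rate, seed = 13)
  total_bases <- nrow(reads) * read_len
  expect_gt(total_bases, 8000)
  observed <- sum(reads$n_errors) / total_bases
  sd3 <- 3 * sqrt(rate * (1 - rate) / total_bases)
  expect_lt(abs(observed - rate), sd3)
  # n_errors truth matches a direct comparison against the source
  for (i in seq_len(min(5, nrow(reads)))) {
    r <- if (reads$strand[[i]] == "-") rc_str(reads$seq[[i]]) else reads$seq[[i]]
    src <- substr(cds, reads$source_start[[i]],
                  reads$source_start[[i]] + read_len - 1L)
    expect_equal(sum(strsplit(r, "")[[1]] != strsplit(src, "")[[1]]),
                 reads$n_errors[[i]])
  }
})

test_that("ortholog pairs plant exact synonymous/non-synonymous counts", {
  g <- fix_genome()
  cds <- g$cds$seq[[5]] # non-duplicate gene, intact reading frame
  same <- generate_ortholog_pair(cds, 0, 0, seed = 1)
  expect_identical(same$cds_a, same$cds_b)
  syn <- generate_ortholog_pair(cds, 3, 0, seed = 2)
  tr <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x)))
  expect_identical(tr(syn$cds_a), tr(syn$cds_b))
  expect_equal(sum(strsplit(syn$cds_a, "")[[1]] != strsplit(syn$cds_b, "")[[1]]), 3)
})

test_that("Ct tables invert to the planted fold-changes at zero noise", {
  pats <- tibble::tibble(gene = c("up", "flat"),
                         pattern = c("immediate_up", "unchanged"),
                         fold_1h = c(400, NA))
  tab <- generate_ct_table(pats, noise_sd = 0, seed = 4)
  folds <- fold_change(expression_profiles(tab$ct), "CK")
  expect_equal(folds$fold[folds$gene == "up" & folds$sample == "1h"], 400)
  expect_equal(folds$fold[folds$gene == "flat"], rep(1, 4))
})
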