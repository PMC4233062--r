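test_that("six-frame translation follows the standard code and drops partial codons", {
  fr <- translate_six_frames("ATGAAA")
  expect_equal(fr$protein[fr$frame == 1], "MK")
  # reverse complement of TTTCAT is ATGAAA
  fr2 <- translate_six_frames("TTTCAT")
  expect_equal(fr2$protein[fr2$frame == -1], "MK")
  fr3 <- translate_six_frames("ATGA")
  expect_equal(fr3$protein[fr3$frame == 1], "M") # partial codon dropped
  expect_equal(fr3$protein[fr3$frame == 2], "*") # TGA stop
  expect_equal(fr3$protein[fr3$frame == 3], "")  # GA alone: no codon
})

test_that("local alignment matches a brute-force Smith-Waterman oracle", {
  set.seed(71)
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (k in 1:20) {
    a <- paste(sample(aas, sample(4:10, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(4:10, 1), replace = TRUE), collapse = "")
    al <- local_align(a, b)
    expect_equal(al$score, sw_oracle(a, b), info = paste(a, b))
    # symmetry
    expect_equal(local_align(b, a)$score, al$score)
  }
  ident <- paste(sample(aas, 20, replace = TRUE), collapse = "")
  al <- local_align(ident, ident)
  expect_equal(al$similarity, 1.0)
  expect_error(local_align("", "AA"), "empty")
})

test_that("homolog search recovers planted homologs and is strand-complete", {
  fam <- fix_family()
  refs <- fam$proteins[1, ]
  cds <- revtrans(refs$seq[[1]], stop = FALSE)
  pool_fwd <- tibble::tibble(id = "fwd", seq = cds, moltype = "dna")
  pool_rc <- tibble::tibble(id = "rc", seq = rc_str(cds), moltype = "dna")
  h_fwd <- search_homologs(refs, pool_fwd)
  h_rc <- search_homologs(refs, pool_rc)
  expect_equal(nrow(h_fwd), 1)
  expect_equal(nrow(h_rc), 1)
  expect_equal(h_fwd$similarity, 1.0)
  expect_equal(h_rc$similarity, 1.0)
  expect_gt(h_fwd$frame, 0)
  expect_lt(h_rc$frame, 0)
  # recovery is invariant under reverse-complementing the pool sequence
  expect_equal(h_fwd$score, h_rc$score)
  expect_equal(h_fwd$subject_start, h_rc$subject_start)
  expect_equal(h_fwd$subject_end, h_rc$subject_end)

  # planted homolog mutated to ~70% amino-acid identity is still recovered
  prot <- strsplit(refs$seq[[1]], "")[[1]]
  set.seed(4)
  pos <- sample(length(prot), round(0.3 * length(prot)))
  prot[pos] <- sample(c("G", "S", "T", "N", "Q", "A"), length(pos), replace = TRUE)
  mut_pool <- tibble::tibble(id = "mut", seq = revtrans(paste(prot, collapse = ""),
                                                        stop = FALSE),
                             moltype = "dna")
  h_mut <- search_homologs(refs, mut_pool)
  expect_equal(nrow(h_mut), 1)

  expect_error(search_homologs(refs, refs[0, ]), "empty pool")
})

test_that("random pools yield no hits at the 60 percent / 60-residue level", {
  fam <- fix_family()
  refs <- fam$proteins[1, ]
  for (s in 1:20) {
    set.seed(1000 + s)
    rand <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
    pool <- tibble::tibble(id = "r", seq = rand, moltype = "dna")
    hits <- search_homologs(refs, pool, min_similarity = 0.60, min_aln_len = 60)
    expect_equal(nrow(hits), 0)
  }
})

test_that("greedy assembly merges overlapping reads and respects tie rules", {
  set.seed(5)
  src <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  r1 <- substr(src, 1, 120)
  r2 <- substr(src, 71, 190) # 50 nt overlap with r1
  two <- assemble_contigs(tibble::tibble(id = c("r1", "r2"), seq = c(r1, r2)),
                          min_overlap = 40)
  expect_equal(nrow(two), 1)
  expect_equal(nchar(two$seq[[1]]), 190)
  expect_equal(two$seq[[1]], substr(src, 1, 190))

  set.seed(6)
  other <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  apart <- assemble_contigs(tibble::tibble(id = c("r1", "r2"), seq = c(r1, other)),
                            min_overlap = 40)
  expect_equal(nrow(apart), 2)
})

test_that("error-free EST sets assemble into the source CDS (property)", {
  g <- fix_genome()
  cds <- g$cds$seq[[5]]
  for (s in 1:12) {
    reads <- generate_ests(cds, coverage = 5, read_len = 100, error_rate = 0,
                           seed = s)
    ctg <- assemble_contigs(reads, min_overlap = 25)
    expect_equal(nrow(ctg), 1, info = paste("seed", s))
    expect_true(ctg$seq[[1]] == cds || rc_str(ctg$seq[[1]]) == cds,
                info = paste("seed", s))
    # consensus is at least as long as the longest member
    expect_gte(nchar(ctg$seq[[1]]), max(nchar(reads$seq)))
  }
  dep <- contig_depth(assemble_contigs(
    generate_ests(cds, coverage = 5, read_len = 100, error_rate = 0, seed = 1),
    min_overlap = 25)[1, ],
    generate_ests(cds, coverage = 5, read_len = 100, error_rate = 0, seed = 1))
  expect_true(all(dep$depth >= 1))
})

test_that("full-length validation requires homology plus both structures", {
  fam <- fix_family()
  refs <- fam$proteins[1:2, ]
  good <- revtrans(fam$proteins$seq[[3]])
  v <- validate_full_length(good, refs, seed = 2)
  expect_true(v$accepted)

  # delete the HR-A/B region: homology remains, structure check fails
  tr <- fam$truth[3, ]
  p <- fam$proteins$seq[[3]]
  no_hr <- paste0(substr(p, 1, tr$hra_start - 1L),
                  substr(p, tr$hrb_end + 15L, nchar(p)))
  v2 <- validate_full_length(revtrans(no_hr), refs, seed = 2)
  expect_false(v2$accepted)
  expect_match(v2$reason, "HR-A/B")

  # unrelated sequence is rejected outright
  set.seed(3)
  junk <- paste(sample(c("G", "S", "T", "N", "Q", "A", "P", "E", "D"),
                       300, replace = TRUE), collapse = "")
  v3 <- validate_full_length(revtrans(junk), refs, seed = 2)
  expect_false(v3$accepted)
})
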