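test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(compute_mw("G"), 75.07, tolerance = 1e-4)
  expect_equal(compute_mw("GG"), 132.12, tolerance = 1e-4)
  expect_error(compute_mw(""), "empty")
  # additivity: mw(a+b) = mw(a) + mw(b) - water
  set.seed(2)
  aas <- c("A", "R", "N", "D", "E", "K", "W", "V")
  for (k in 1:5) {
    a <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 5, replace = TRUE), collapse = "")
    expect_equal(compute_mw(paste0(a, b)),
                 compute_mw(a) + compute_mw(b) - 18.0153)
  }
})

test_that("isoelectric point zeroes the net charge and orders basic vs acidic", {
  for (p in c("EEKK", "ARNDCEQGHK", strrep("K", 10), strrep("D", 10))) {
    pi <- compute_pi(p)
    expect_lt(abs(protein_charge(p, pi)), 1e-3)
  }
  expect_gt(compute_pi(strrep("K", 10)), compute_pi(strrep("D", 10)))
  # bisection agrees with an independent fine-grid scan of the same charge
  expect_equal(compute_pi("EEKK"), pi_grid_oracle("EEKK"), tolerance = 1e-3)
})

test_that("the DBD profile scan localizes planted domains and rejects shuffles", {
  fam <- fix_family()
  ann <- fam$annotation
  tr <- fam$truth
  for (i in seq_len(nrow(tr))) {
    expect_false(is.na(ann$dbd_start[[i]]))
    ov <- min(ann$dbd_end[[i]], tr$dbd_end[[i]]) -
      max(ann$dbd_start[[i]], tr$dbd_start[[i]]) + 1L
    expect_gte(ov / (tr$dbd_end[[i]] - tr$dbd_start[[i]] + 1L), 0.9)
    # full profile hits span 94 residues
    expect_equal(ann$dbd_end[[i]] - ann$dbd_start[[i]] + 1L, 94L)
  }
  # shuffling the protein destroys the signal
  p <- fam$proteins$seq[[1]]
  for (s in 1:20) {
    set.seed(3000 + s)
    shuf <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    expect_equal(nrow(detect_dbd(shuf, seed = s)), 0, info = paste("seed", s))
  }
})

test_that("heptad detection recovers the planted 21/0/7 insertions exactly", {
  for (cls in c("A", "B", "C")) {
    for (s in 1:50) {
      res <- generate_hsf_protein(cls, seed = 10000 + s)
      hr <- detect_hrab(res$protein$seq[[1]], res$truth$dbd_end)
      expect_equal(nrow(hr), 1)
      expect_equal(hr$insertion, c(A = 21L, B = 0L, C = 7L)[[cls]],
                   ignore_attr = TRUE, info = paste(cls, s))
      expect_equal(hr$hra_start, res$truth$hra_start, info = paste(cls, s))
    }
  }
  # no heptad blocks -> no call
  expect_equal(nrow(detect_hrab(strrep("GSTNQ", 40), 10)), 0)
})

test_that("NLS detection reports basic clusters with one allowed interruption", {
  ctx <- paste0(strrep("Q", 247), "KKRRLK", strrep("S", 30))
  hit <- find_nls(ctx)
  expect_equal(hit$position, 248L)
  expect_equal(hit$motif, "KKRRLK")
  expect_equal(nrow(find_nls("KARAK")), 0)
  h2 <- find_nls("KKRR")
  expect_equal(h2$position, 1L)
})

test_that("NES detection is canonical-aware and restricted to the C-terminus", {
  p <- paste0(strrep("Q", 200), "LTEQMGLL", strrep("S", 20))
  h <- find_nes(p)
  expect_true(any(h$canonical))
  expect_equal(h$position[h$canonical][[1]], 201L)
  pb <- paste0(strrep("Q", 200), "LRLNLM", strrep("S", 10))
  hb <- find_nes(pb)
  expect_true(any(hb$canonical))
  # a leucine-rich run in the N-terminal region is not an export signal
  pn <- paste0("LTEQMGLL", strrep("Q", 300))
  expect_equal(nrow(find_nes(pn)), 0)
})

test_that("AHA windows require composition, an aromatic and an acidic residue", {
  p <- paste0(strrep("G", 50), "DVFWEQFLTEVG", strrep("G", 10))
  h <- find_aha(p)
  expect_equal(nrow(h), 1)
  expect_equal(h$score, 9 / 12) # hand count: D,V,F,W,E,F,L,E,V of 12
  expect_equal(nrow(find_aha(strrep("A", 40))), 0)
  # aromatic-only window without an acidic residue is rejected
  expect_equal(nrow(find_aha(paste0(strrep("G", 30), "WWFFLLIIVVLL",
                                    strrep("G", 10)))), 0)
})

test_that("localization prediction follows the NLS/NES rule", {
  loc <- predict_localization(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
  expect_equal(loc$localization,
               c("nucleus", "nucleus+cytoplasm", "nucleus+cytoplasm"))
  expect_equal(loc$low_confidence, c(FALSE, FALSE, TRUE))
})

test_that("annotation respects the linker convention on planted proteins", {
  fam <- fix_family()
  ann <- fam$annotation
  ok <- !is.na(ann$hra_start)
  expect_true(all(ok))
  expect_true(all(ann$dbd_end[ok] < ann$hra_start[ok]))
  expect_equal(ann$linker_length[ok], ann$hra_start[ok] - ann$dbd_end[ok])
})
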