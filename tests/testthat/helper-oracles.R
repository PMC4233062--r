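# Independent oracles and shared fixtures for the test suite.

# deterministic reverse translation (first codon per amino acid)
aa2codon <- vapply(split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE),
                   `[`, character(1), 1)
revtrans <- function(protein, stop = TRUE) {
  paste0(paste(aa2codon[strsplit(protein, "")[[1]]], collapse = ""),
         if (stop) "TAA" else "")
}

rc_str <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# brute-force Smith-Waterman with affine gaps (independent of Biostrings)
sw_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  sub <- local({
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    env$BLOSUM62
  })
  cha <- strsplit(a, "")[[1]]
  chb <- strsplit(b, "")[[1]]
  n <- length(cha)
  m <- length(chb)
  M <- matrix(0, n + 1, m + 1)       # match state
  X <- matrix(-Inf, n + 1, m + 1)    # gap in b
  Y <- matrix(-Inf, n + 1, m + 1)    # gap in a
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      s <- sub[cha[i], chb[j]]
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) + s)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# brute-force free-end-gap global alignment (linear gap penalty) with
# traceback, computing coverage and similarity the way the 80/80 rule
# defines them: aligned columns over the longer sequence, identities over
# aligned columns
overlap_oracle <- function(a, b, match = 2, mismatch = -3, gap = 7) {
  cha <- strsplit(a, "")[[1]]
  chb <- strsplit(b, "")[[1]]
  n <- length(cha)
  m <- length(chb)
  S <- matrix(0, n + 1, m + 1) # free leading gaps
  P <- matrix(0L, n + 1, m + 1) # 1 diag, 2 up (gap in b), 3 left (gap in a)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (cha[i] == chb[j]) match else mismatch
      u <- S[i, j + 1] - gap
      l <- S[i + 1, j] - gap
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- which.max(c(d, u, l))
    }
  }
  # free trailing gaps: best cell on last row or column
  ends <- rbind(cbind(rep(n + 1, m + 1), seq_len(m + 1)),
                cbind(seq_len(n + 1), rep(m + 1, n + 1)))
  vals <- S[ends]
  e <- ends[which.max(vals), ]
  i <- e[[1]]; j <- e[[2]]
  cols <- 0L
  matches <- 0L
  while (i > 1 && j > 1) {
    p <- P[i, j]
    cols <- cols + 1L
    if (p == 1L) {
      if (cha[i - 1] == chb[j - 1]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(coverage = cols / max(n, m),
       similarity = if (cols > 0) matches / cols else 0)
}

# fine-grid isoelectric point oracle
pi_grid_oracle <- function(protein, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  q <- hsfkit::protein_charge(protein, ph)
  ph[which.min(abs(q))]
}

# cached expensive fixtures (built once per test run)
.fixture_env <- new.env()
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fix_family <- function() {
  fixture("family", function() {
    fam <- generate_hsf_family(n_a = 4, n_b = 3, n_c = 2, seed = 42)
    fam$annotation <- annotate_hsf(fam$proteins, seed = 5)
    fam
  })
}

fix_genome <- function() {
  fixture("genome", function() {
    generate_family_genome(
      n_genes = 10, n_chromosomes = 4,
      dup_pairs = list(c(0.95, 0.95), c(0.70, 0.90)),
      tandem_cluster_size = 3, seed = 11)
  })
}
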