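#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da). The residue
#' mass table ships with the package (`inst/extdata/aa_average_masses.tsv`)
#' so the computation is pinned, not delegated to an online calculator.
#'
#' @param protein Amino-acid sequence string.
#' @return Mass in Daltons.
#' @examples
#' compute_mw("G") # 75.07
#' @export
compute_mw <- function(protein) {
  if (!nzchar(protein)) abort("empty protein sequence")
  masses <- aa_mass_table()
  ch <- seq_chars(toupper(protein))
  unknown <- setdiff(unique(ch), names(masses))
  if (length(unknown) > 0L) {
    abort(paste0("residue(s) without a mass entry: ", paste(unknown, collapse = "")))
  }
  sum(masses[ch]) + 18.0153
}

aa_mass_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- readr::read_tsv(hsf_extdata("aa_average_masses.tsv"),
                             col_types = "cd", progress = FALSE)
      cache <<- setNames(tab$mass, tab$residue)
    }
    cache
  }
})

pka_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- readr::read_tsv(hsf_extdata("pka_bjellqvist.tsv"),
                                col_types = "cdd", progress = FALSE)
    }
    cache
  }
})

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable side chains (D, E, C, Y, H,
#' K, R) and the two termini, using the packaged pKa set.
#'
#' @param protein Amino-acid sequence string.
#' @param ph pH value (may be a vector).
#' @return Net charge at each `ph`.
#' @export
protein_charge <- function(protein, ph) {
  ch <- seq_chars(toupper(protein))
  pka <- pka_table()
  counts <- setNames(rep(0, nrow(pka)), pka$group)
  for (g in pka$group) {
    counts[[g]] <- if (g %in% c("Nterm", "Cterm")) 1 else sum(ch == g)
  }
  vapply(ph, function(p) {
    q <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[[i]]
      if (counts[[g]] == 0) next
      if (pka$charge[[i]] > 0) {
        q <- q + counts[[g]] / (1 + 10^(p - pka$pka[[i]]))
      } else {
        q <- q - counts[[g]] / (1 + 10^(pka$pka[[i]] - p))
      }
    }
    q
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Solves `protein_charge(protein, pH) = 0` by bisection on pH in (0, 14) to
#' the requested tolerance. The termini guarantee a sign change on that
#' interval.
#'
#' @param protein Amino-acid sequence string.
#' @param tol Half-width of the final bracket in pH units (default 1e-3).
#' @return The isoelectric point (pH units).
#' @export
compute_pi <- function(protein, tol = 1e-3) {
  if (!nzchar(protein)) abort("empty protein sequence")
  lo <- 0
  hi <- 14
  if (protein_charge(protein, lo) < 0 || protein_charge(protein, hi) > 0) {
    abort("net charge does not change sign on (0, 14)")
  }
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (protein_charge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physical properties for a set of proteins
#'
#' @param proteins Sequence tibble (columns `id`, `seq`).
#' @return A tibble with `id`, `length`, `pi`, `mw`.
#' @export
protein_properties <- function(proteins) {
  tibble(
    id = proteins$id,
    length = nchar(proteins$seq),
    pi = vapply(proteins$seq, compute_pi, numeric(1), USE.NAMES = FALSE),
    mw = vapply(proteins$seq, compute_mw, numeric(1), USE.NAMES = FALSE)
  )
}

# ---- DBD profile ----------------------------------------------------------

# Secondary-structure layout of the canonical Hsf DNA-binding domain:
# four beta strands packed against three alpha helices, 94 columns in the
# full-length profile. The consensus is built deterministically by cycling
# region-specific alphabets; no biological sequence is copied.
DBD_LAYOUT <- list(
  list(kind = "strand", len = 8),  # beta-1
  list(kind = "loop",   len = 4),
  list(kind = "helix",  len = 15), # alpha-1
  list(kind = "loop",   len = 4),
  list(kind = "strand", len = 7),  # beta-2
  list(kind = "helix",  len = 15), # alpha-2
  list(kind = "loop",   len = 4),
  list(kind = "strand", len = 6),  # beta-3
  list(kind = "helix",  len = 17), # alpha-3
  list(kind = "loop",   len = 5),
  list(kind = "strand", len = 9)   # beta-4
)

DBD_REGION_ALPHABET <- list(
  strand = c("V", "I", "F", "Y", "T", "W"),
  helix  = c("E", "A", "L", "K", "Q", "R", "D", "M"),
  loop   = c("G", "P", "S", "N", "D", "T")
)

#' Position-weight profile of the Hsf DNA-binding domain
#'
#' A 20 x 94 column-stochastic matrix built from the canonical DBD
#' secondary-structure layout (four-stranded beta-sheet against three
#' alpha-helices). Each column puts probability `p_consensus` on the
#' consensus residue, `p_region` spread over the region alphabet and the
#' remainder spread uniformly over all twenty residues. The construction is
#' deterministic (alphabet cycling), so the profile is reproducible without
#' any packaged alignment.
#'
#' @param p_consensus Probability mass on the consensus residue (default 0.6).
#' @param p_region Probability mass spread over the region alphabet (0.3).
#' @return A numeric matrix with rownames the 20 amino acids, 94 columns,
#'   plus attributes `consensus` (string).
#' @export
hsf_dbd_profile <- function(p_consensus = 0.6, p_region = 0.3) {
  consensus <- character(0)
  kinds <- character(0)
  for (reg in DBD_LAYOUT) {
    alpha <- DBD_REGION_ALPHABET[[reg$kind]]
    consensus <- c(consensus, alpha[((seq_len(reg$len) - 1L) %% length(alpha)) + 1L])
    kinds <- c(kinds, rep(reg$kind, reg$len))
  }
  n <- length(consensus) # 94
  p_bg <- 1 - p_consensus - p_region
  prof <- matrix(p_bg / 20, nrow = 20, ncol = n, dimnames = list(AA20, NULL))
  for (j in seq_len(n)) {
    alpha <- DBD_REGION_ALPHABET[[kinds[[j]]]]
    prof[alpha, j] <- prof[alpha, j] + p_region / length(alpha)
    prof[consensus[[j]], j] <- prof[consensus[[j]], j] + p_consensus
  }
  attr(prof, "consensus") <- paste(consensus, collapse = "")
  prof
}

profile_logodds <- function(profile, background = 1 / 20) {
  log2(profile / background)
}

score_windows <- function(idx, lod) {
  w <- ncol(lod)
  n_off <- length(idx) - w + 1L
  if (n_off < 1L) return(numeric(0))
  total <- numeric(n_off)
  for (j in seq_len(w)) { # column-wise shifted accumulation
    v <- lod[cbind(idx[j:(j + n_off - 1L)], j)]
    v[is.na(v)] <- 0 # unknown residues score neutral
    total <- total + v
  }
  total
}

#' Detect the DNA-binding domain with a position-weight profile
#'
#' Scores every window of the profile length along the protein (log-odds vs
#' a uniform background) plus N-terminally truncated profile hits anchored
#' at position 1 (down to 83 columns, admitting the short DBD variants).
#' The detection threshold is calibrated per call as the 99.9th percentile
#' of best-window scores over shuffled copies of the protein.
#'
#' @param protein Amino-acid sequence string.
#' @param profile Profile matrix from [hsf_dbd_profile()].
#' @param n_shuffle Number of shuffles for threshold calibration (default 200).
#' @param min_len Shortest admissible truncated profile (default 83).
#' @param seed Seed for the shuffle calibration (default 1).
#' @return A one-row tibble `start`, `end`, `score`, or a zero-row tibble if
#'   no window clears the calibrated threshold.
#' @export
detect_dbd <- function(protein, profile = hsf_dbd_profile(), n_shuffle = 200,
                       min_len = 83, seed = 1) {
  none <- tibble(start = integer(0), end = integer(0), score = numeric(0))
  ch <- seq_chars(toupper(protein))
  idx <- match(ch, AA20)
  lod <- profile_logodds(profile)
  w <- ncol(lod)

  # calibrate on shuffled residues
  shuffle_max <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      s <- sample(idx)
      sc <- score_windows(s, lod)
      if (length(sc) == 0) -Inf else max(sc)
    }, numeric(1))
  })
  threshold <- quantile(shuffle_max, 0.999, names = FALSE, type = 7)

  # candidate windows carry a length-scaled copy of the calibrated
  # threshold; thresholds can be negative (log-odds), so candidates are
  # filtered by score minus threshold, never by a ratio
  cand <- tibble(start = integer(0), end = integer(0), score = numeric(0),
                 thr = numeric(0))
  full <- score_windows(idx, lod)
  if (length(full) > 0) {
    best <- which.max(full)
    cand <- dplyr::bind_rows(cand, tibble(
      start = best, end = best + w - 1L, score = full[[best]], thr = threshold))
  }
  # N-terminal truncation: profile suffix anchored at protein position 1
  if (length(ch) >= min_len) {
    for (len in seq(min_len, min(w - 1L, length(ch)))) {
      sub <- lod[, (w - len + 1L):w, drop = FALSE]
      rows <- idx[seq_len(len)]
      ok <- !is.na(rows)
      sc <- sum(sub[cbind(rows[ok], which(ok))])
      cand <- dplyr::bind_rows(cand, tibble(
        start = 1L, end = len, score = sc, thr = threshold * len / w))
    }
  }
  cand <- cand[cand$score > cand$thr & cand$score > 0, , drop = FALSE]
  if (nrow(cand) == 0) return(none)
  best <- cand[which.max(cand$score - cand$thr), c("start", "end", "score")]
  best$start <- as.integer(best$start)
  best$end <- as.integer(best$end)
  best
}

# ---- heptad repeats -------------------------------------------------------

#' Detect the HR-A/B oligomerization region
#'
#' Scans C-terminal of the DBD for two blocks of hydrophobic heptad repeats
#' (core residues from L/I/V/M/F spaced exactly seven apart, at least three
#' cores per block). The insertion length is the number of residues strictly
#' between the last HR-A core and the first HR-B core; it is snapped to the
#' nearest of the class signatures {0, 7, 21} when within +/-2, with the raw
#' value retained as evidence.
#'
#' @param protein Amino-acid sequence string.
#' @param dbd_end 1-based position of the last DBD residue.
#' @return A one-row tibble with `hra_start`, `hra_end`, `hrb_start`,
#'   `hrb_end`, `insertion_raw`, `insertion` (NA when unsnappable), or a
#'   zero-row tibble when two heptad blocks are not found.
#' @export
detect_hrab <- function(protein, dbd_end) {
  none <- tibble(hra_start = integer(0), hra_end = integer(0),
                 hrb_start = integer(0), hrb_end = integer(0),
                 insertion_raw = integer(0), insertion = integer(0))
  ch <- seq_chars(toupper(protein))
  hyd <- ch %in% HYDROPHOBIC_CORE
  n <- length(ch)
  runs <- list()
  for (i in seq_len(n)) {
    if (!hyd[[i]]) next
    if (i > 7 && hyd[[i - 7]]) next # not a chain start
    k <- 0L
    while (i + 7L * (k + 1L) <= n && hyd[[i + 7L * (k + 1L)]]) k <- k + 1L
    if (k >= 2L) runs[[length(runs) + 1L]] <- c(start = i, end = i + 7L * k)
  }
  if (length(runs) == 0) return(none)
  runs <- do.call(rbind, runs)
  runs <- runs[order(runs[, "start"]), , drop = FALSE]
  a <- which(runs[, "start"] > dbd_end)
  if (length(a) == 0) return(none)
  a <- a[[1]]
  b <- which(runs[, "start"] > runs[a, "end"])
  if (length(b) == 0) return(none)
  b <- b[[1]]
  raw <- as.integer(runs[b, "start"] - runs[a, "end"] - 1L)
  sigs <- c(0L, 7L, 21L)
  snapped <- sigs[which.min(abs(sigs - raw))]
  if (abs(snapped - raw) > 2L) snapped <- NA_integer_
  tibble(hra_start = as.integer(runs[a, "start"]), hra_end = as.integer(runs[a, "end"]),
         hrb_start = as.integer(runs[b, "start"]), hrb_end = as.integer(runs[b, "end"]),
         insertion_raw = raw, insertion = snapped)
}

# ---- short motifs ---------------------------------------------------------

#' Find nuclear localization signals (basic K/R clusters)
#'
#' Reports maximal stretches built from K/R runs with at most one internal
#' non-K/R residue and at least three K/R residues in total, starting after
#' `after` (typically the DBD end).
#'
#' @param protein Amino-acid sequence string.
#' @param after Only report hits starting after this position (default 0).
#' @return Tibble with `position` (1-based start) and `motif`.
#' @export
find_nls <- function(protein, after = 0) {
  s <- toupper(protein)
  m <- gregexpr("[KR]+(?:[^KR][KR]+)?", s, perl = TRUE)[[1]]
  out <- tibble(position = integer(0), motif = character(0))
  if (m[[1]] == -1) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    motif <- substr(s, starts[[i]], starts[[i]] + lens[[i]] - 1L)
    n_kr <- sum(seq_chars(motif) %in% c("K", "R"))
    if (n_kr >= 3L && starts[[i]] > after) {
      out <- dplyr::bind_rows(out, tibble(position = starts[[i]], motif = motif))
    }
  }
  out
}

#' Find nuclear export signals (leucine-rich C-terminal motifs)
#'
#' Matches a generalized leucine-rich export pattern
#' `phi-x(1,3)-phi-x(1,3)-phi-x(0,1)-phi` (phi in L/I/V/M/F) restricted to
#' the C-terminal 30 percent of the protein. Exact matches to the canonical
#' Hsf export motifs `LTEQMGLL` and `(L/I)(G/R)LNLM` are flagged.
#'
#' @param protein Amino-acid sequence string.
#' @return Tibble with `position`, `motif`, `canonical`.
#' @export
find_nes <- function(protein) {
  s <- toupper(protein)
  n <- nchar(s)
  cutoff <- floor(0.7 * n)
  out <- tibble(position = integer(0), motif = character(0), canonical = logical(0))
  pat <- "[LIVMF][^LIVMF]{1,3}[LIVMF][^LIVMF]{1,3}[LIVMF][^LIVMF]{0,1}[LIVMF]"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[[1]] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      if (starts[[i]] <= cutoff) next
      motif <- substr(s, starts[[i]], starts[[i]] + lens[[i]] - 1L)
      out <- dplyr::bind_rows(out, tibble(
        position = starts[[i]], motif = motif,
        canonical = grepl("L[A-Z][ED]QMG[A-Z][LR]", motif) ||
          grepl("[LI][GR]LNLM", motif)))
    }
  }
  # canonical motifs are reported even if the generic scan merged past them;
  # the first pattern covers the LTEQMGLL-type class-A export signal family
  for (pat2 in c("L[A-Z][ED]QMG[A-Z][LR]", "[LI][GR]LNLM")) {
    m2 <- gregexpr(pat2, s, perl = TRUE)[[1]]
    if (m2[[1]] == -1) next
    for (i in seq_along(m2)) {
      pos <- as.integer(m2[[i]])
      if (pos <= cutoff) next
      motif <- substr(s, pos, pos + attr(m2, "match.length")[[i]] - 1L)
      if (!any(out$position <= pos & pos <= out$position + nchar(out$motif) - 1L &
                 out$canonical)) {
        out <- dplyr::bind_rows(out, tibble(position = pos, motif = motif,
                                            canonical = TRUE))
      }
    }
  }
  dplyr::arrange(dplyr::distinct(out), .data$position)
}

#' Find AHA activator motifs
#'
#' Slides a window over the region C-terminal of the HR-B block and scores
#' the fraction of aromatic (W/F/Y), large hydrophobic (L/I/V) and acidic
#' (E/D) residues. A window is a hit when the score is at least
#' `min_score` and the window contains at least one aromatic and one acidic
#' residue; overlapping hit windows are merged.
#'
#' @param protein Amino-acid sequence string.
#' @param window Window width (default 12).
#' @param after Only scan after this position (e.g. HR-B end; default 0).
#' @param min_score Composition-score threshold (default 0.6).
#' @return Tibble with `position`, `motif` (merged region), `score` (best
#'   window score in the region).
#' @export
find_aha <- function(protein, window = 12, after = 0, min_score = 0.6) {
  s <- toupper(protein)
  ch <- seq_chars(s)
  n <- length(ch)
  out <- tibble(position = integer(0), motif = character(0), score = numeric(0))
  if (n < window) return(out)
  favored <- ch %in% c("W", "F", "Y", "L", "I", "V", "E", "D")
  aromatic <- ch %in% c("W", "F", "Y")
  acidic <- ch %in% c("E", "D")
  starts <- seq_len(n - window + 1L)
  starts <- starts[starts > after]
  hit <- logical(0)
  scores <- numeric(0)
  for (o in starts) {
    idxw <- o:(o + window - 1L)
    sc <- sum(favored[idxw]) / window
    hit <- c(hit, sc >= min_score && any(aromatic[idxw]) && any(acidic[idxw]))
    scores <- c(scores, sc)
  }
  if (!any(hit)) return(out)
  hs <- starts[hit]
  hsc <- scores[hit]
  grp <- cumsum(c(1L, diff(hs) > window))
  for (g in unique(grp)) {
    pos <- hs[grp == g]
    first <- min(pos)
    last <- max(pos) + window - 1L
    out <- dplyr::bind_rows(out, tibble(
      position = first,
      motif = substr(s, first, last),
      score = max(hsc[grp == g])))
  }
  out
}

#' Predict subcellular localization from the domain annotation
#'
#' NLS without NES predicts strictly nuclear accumulation; NLS plus NES
#' predicts nucleocytoplasmic shuttling. Proteins without a detected NLS are
#' reported as shuttling with a low-confidence flag (export cannot be ruled
#' out without an import signal to anchor the call).
#'
#' @param has_nls,has_nes Logical vectors.
#' @return Tibble with `localization` and `low_confidence`.
#' @export
predict_localization <- function(has_nls, has_nes) {
  tibble(
    localization = ifelse(has_nls & !has_nes, "nucleus", "nucleus+cytoplasm"),
    low_confidence = !has_nls
  )
}

#' Annotate the Hsf domain architecture of a protein set
#'
#' Runs the full detector suite (DBD profile scan, HR-A/B heptad blocks,
#' NLS/NES/AHA motifs, localization prediction) over a sequence tibble and
#' returns one row per protein with the domain-table column semantics:
#' `linker_length` is `hra_start - dbd_end`.
#'
#' @param proteins Sequence tibble (columns `id`, `seq`).
#' @param profile DBD profile (default [hsf_dbd_profile()]).
#' @param seed Seed for the DBD threshold calibration.
#' @return A tibble with one row per protein.
#' @export
annotate_hsf <- function(proteins, profile = hsf_dbd_profile(), seed = 1) {
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    id <- proteins$id[[i]]
    s <- proteins$seq[[i]]
    dbd <- detect_dbd(s, profile = profile, seed = seed)
    if (nrow(dbd) == 0) {
      return(tibble(id = id, dbd_start = NA_integer_, dbd_end = NA_integer_,
                    dbd_score = NA_real_, linker_length = NA_integer_,
                    hra_start = NA_integer_, hra_end = NA_integer_,
                    hrb_start = NA_integer_, hrb_end = NA_integer_,
                    insertion_raw = NA_integer_, insertion = NA_integer_,
                    nls = NA_character_, nes = NA_character_,
                    aha = NA_character_, localization = NA_character_))
    }
    hr <- detect_hrab(s, dbd$end)
    nls <- find_nls(s, after = dbd$end)
    nes <- find_nes(s)
    aha_after <- if (nrow(hr) > 0) hr$hrb_end else dbd$end
    aha <- find_aha(s, after = aha_after)
    fmt <- function(tb) {
      if (nrow(tb) == 0) NA_character_ else
        paste(sprintf("(%d)%s", tb$position, tb$motif), collapse = " ")
    }
    loc <- predict_localization(nrow(nls) > 0, nrow(nes) > 0)
    tibble(
      id = id,
      dbd_start = dbd$start, dbd_end = dbd$end, dbd_score = dbd$score,
      linker_length = if (nrow(hr) > 0) hr$hra_start - dbd$end else NA_integer_,
      hra_start = if (nrow(hr) > 0) hr$hra_start else NA_integer_,
      hra_end = if (nrow(hr) > 0) hr$hra_end else NA_integer_,
      hrb_start = if (nrow(hr) > 0) hr$hrb_start else NA_integer_,
      hrb_end = if (nrow(hr) > 0) hr$hrb_end else NA_integer_,
      insertion_raw = if (nrow(hr) > 0) hr$insertion_raw else NA_integer_,
      insertion = if (nrow(hr) > 0) hr$insertion else NA_integer_,
      nls = fmt(nls), nes = fmt(nes), aha = fmt(aha),
      localization = loc$localization
    )
  })
}
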