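# In-silico cloning stage: translated homology search against an EST pool,
# greedy contig assembly, and full-length validation of candidates.

# Karlin-Altschul parameters for BLOSUM62 with affine gaps (open 11, extend 1)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Translate a nucleotide sequence in all six frames
#'
#' Standard codon table; the trailing partial codon is dropped; stop codons
#' appear as `*`. Ambiguous codons (containing N) translate to `X`.
#'
#' @param nt Nucleotide sequence string (or one-row sequence tibble).
#' @return A tibble with `frame` (+1..+3, -1..-3) and `protein`.
#' @export
translate_six_frames <- function(nt) {
  if (is.data.frame(nt)) nt <- nt$seq[[1]]
  nt <- toupper(nt)
  rc <- revcomp(nt)
  one <- function(s, off) {
    sub <- substr(s, off, nchar(s))
    sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
    if (nchar(sub) == 0L) return("")
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "solve")))
  }
  tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    protein = c(one(nt, 1L), one(nt, 2L), one(nt, 3L),
                one(rc, 1L), one(rc, 2L), one(rc, 3L))
  )
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps (via Biostrings). Similarity is the
#' fraction of aligned columns (gap columns included) whose substitution
#' score is positive — the "Positives" convention of translated homology
#' searches. A score of 0 with empty alignment strings is returned when no
#' positive-scoring local alignment exists.
#'
#' @param a,b Protein sequence strings.
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is packaged).
#' @param gap_open,gap_extend Affine gap penalties (positive; default 11/1).
#' @return A one-row tibble `score`, `similarity`, `aligned_a`, `aligned_b`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `aligned_length`.
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("empty sequence in local_align")
  if (matrix != "BLOSUM62") abort("only BLOSUM62 is packaged")
  sub <- blosum62()
  # X (ambiguous translation) scores neutral via the matrix's X row
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = gap_open, gapExtension = gap_extend,
    type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(tibble(score = 0, similarity = NA_real_, aligned_a = "", aligned_b = "",
                  start_a = NA_integer_, end_a = NA_integer_,
                  start_b = NA_integer_, end_b = NA_integer_,
                  aligned_length = 0L))
  }
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ch_a <- seq_chars(al_a)
  ch_b <- seq_chars(al_b)
  pos <- mapply(function(x, y) {
    if (x == "-" || y == "-") return(FALSE)
    x %in% rownames(sub) && y %in% colnames(sub) && sub[x, y] > 0
  }, ch_a, ch_b)
  tibble(
    score = sc,
    similarity = mean(pos),
    aligned_a = al_a, aligned_b = al_b,
    start_a = Biostrings::start(Biostrings::pattern(pa)),
    end_a = Biostrings::end(Biostrings::pattern(pa)),
    start_b = Biostrings::start(Biostrings::subject(pa)),
    end_b = Biostrings::end(Biostrings::subject(pa)),
    aligned_length = length(ch_a)
  )
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the packaged gapped BLOSUM62
#' parameters (lambda 0.267, K 0.041).
#'
#' @param score Alignment score.
#' @param m,n Effective query and subject lengths (residues).
#' @return Expected number of chance alignments with at least this score.
#' @export
karlin_altschul_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Search a nucleotide pool for homologs of reference proteins
#'
#' Translated homology search: every pool sequence is translated in six
#' frames and locally aligned to every reference protein. A hit is reported
#' when the similarity over the aligned region reaches `min_similarity`, the
#' Karlin-Altschul E-value is at most `max_evalue`, and the alignment spans
#' at least `min_aln_len` residues. Subject coordinates are 1-based on the
#' nucleotide sequence, frame-signed for the strand.
#'
#' @param refs Protein sequence tibble (`id`, `seq`).
#' @param pool Nucleotide sequence tibble (`id`, `seq`).
#' @param min_similarity Minimum positives fraction (default 0.60).
#' @param max_evalue Maximum E-value (default 1e-4).
#' @param min_aln_len Minimum aligned length in residues (default 30).
#' @return A tibble of hits: `query_id`, `subject_id`, `frame`,
#'   `subject_start`, `subject_end`, `score`, `similarity`, `evalue`.
#' @export
search_homologs <- function(refs, pool, min_similarity = 0.60,
                            max_evalue = 1e-4, min_aln_len = 30) {
  if (nrow(pool) == 0) abort("empty pool")
  hits <- list()
  for (pi in seq_len(nrow(pool))) {
    frames <- translate_six_frames(pool$seq[[pi]])
    nt_len <- nchar(pool$seq[[pi]])
    for (fi in seq_len(nrow(frames))) {
      prot <- frames$protein[[fi]]
      if (nchar(prot) < min_aln_len) next
      frame <- frames$frame[[fi]]
      for (ri in seq_len(nrow(refs))) {
        al <- local_align(refs$seq[[ri]], prot)
        if (al$score <= 0 || al$aligned_length < min_aln_len) next
        if (is.na(al$similarity) || al$similarity < min_similarity) next
        ev <- karlin_altschul_evalue(al$score, nchar(refs$seq[[ri]]), nchar(prot))
        if (ev > max_evalue) next
        off <- abs(frame)
        if (frame > 0) {
          nt_start <- off + 3L * (al$start_b - 1L)
          nt_end <- off + 3L * al$end_b - 1L
        } else {
          # coordinates on the forward strand of the pool sequence
          rc_start <- off + 3L * (al$start_b - 1L)
          rc_end <- off + 3L * al$end_b - 1L
          nt_start <- nt_len - rc_end + 1L
          nt_end <- nt_len - rc_start + 1L
        }
        hits[[length(hits) + 1L]] <- tibble(
          query_id = refs$id[[ri]], subject_id = pool$id[[pi]], frame = frame,
          subject_start = nt_start, subject_end = nt_end,
          score = al$score, similarity = al$similarity, evalue = ev)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(query_id = character(0), subject_id = character(0),
                  frame = integer(0), subject_start = integer(0),
                  subject_end = integer(0), score = numeric(0),
                  similarity = numeric(0), evalue = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(hits), .data$evalue)
}

anchor_positions <- function(needle, haystack) {
  m <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (m[[1]] == -1) integer(0) else as.integer(m)
}

# longest suffix(a)/prefix(b) overlap at the given identity. Candidate
# lengths are anchored on exact 16-mers (b's first 16 bases located in a,
# and a's last 16 bases located in b) plus the sub-16 tail, then verified
# with the mismatch budget.
best_overlap <- function(a_str, cha, b_str, chb, min_overlap, min_identity) {
  na <- length(cha)
  nb <- length(chb)
  max_len <- min(na, nb)
  if (max_len < min_overlap) return(0L)
  k <- min(16L, nb, na)
  lens <- integer(0)
  lens <- c(lens, na - anchor_positions(substr(b_str, 1L, k), a_str) + 1L)
  lens <- c(lens, anchor_positions(substr(a_str, na - k + 1L, na), b_str) + k - 1L)
  if (min_overlap < k) lens <- c(lens, seq(min_overlap, k - 1L))
  lens <- sort(unique(lens[lens >= min_overlap & lens <= max_len]),
               decreasing = TRUE)
  for (len in lens) {
    mism <- sum(cha[(na - len + 1L):na] != chb[seq_len(len)])
    if (mism / len <= 1 - min_identity) return(len)
  }
  0L
}

# best way to join item b onto the 3' end of item a, allowing either item
# to be reverse-complemented; containment of b in a is a merge of length
# nchar(b)
pair_merge <- function(a, b, min_overlap, min_identity) {
  best <- NULL
  for (ao in c("fwd", "rc")) {
    aseq <- if (ao == "fwd") a$seq else a$rcseq
    cha <- if (ao == "fwd") a$cha else a$chrc
    for (bo in c("fwd", "rc")) {
      bseq <- if (bo == "fwd") b$seq else b$rcseq
      chb <- if (bo == "fwd") b$cha else b$chrc
      cand <- NULL
      if (nchar(bseq) <= nchar(aseq) && grepl(bseq, aseq, fixed = TRUE)) {
        cand <- list(len = nchar(bseq), type = "contain", aorient = ao,
                     borient = bo)
      } else {
        ov <- best_overlap(aseq, cha, bseq, chb, min_overlap, min_identity)
        if (ov > 0L) {
          cand <- list(len = ov, type = "overlap", aorient = ao, borient = bo)
        }
      }
      if (!is.null(cand) &&
          (is.null(best) || cand$len > best$len ||
           (cand$len == best$len &&
            paste(cand$aorient, cand$borient) < paste(best$aorient, best$borient)))) {
        best <- cand
      }
    }
  }
  best %||% list(len = 0L, type = "", aorient = "", borient = "")
}

#' Greedy overlap assembly of reads into contigs
#'
#' Longest-overlap-first merging with deterministic lexicographic
#' tie-breaks. Reads are considered in both orientations; a read contained
#' in a growing contig is absorbed. Unmergeable reads become singleton
#' contigs.
#'
#' @param reads Sequence tibble (`id`, `seq`).
#' @param min_overlap Minimum suffix/prefix overlap (default 40 nt).
#' @param min_identity Minimum identity over the overlap (default 0.95).
#' @return A tibble of contigs: `id`, `seq`, `n_reads`, `members`
#'   (list-column of read ids).
#' @export
assemble_contigs <- function(reads, min_overlap = 40, min_identity = 0.95) {
  if (nrow(reads) == 0) {
    return(tibble(id = character(0), seq = character(0), n_reads = integer(0),
                  members = list()))
  }
  make_item <- function(id, seqs, members) {
    seqs <- toupper(seqs)
    rc <- revcomp(seqs)
    list(id = id, seq = seqs, rcseq = rc,
         cha = seq_chars(seqs), chrc = seq_chars(rc), members = members)
  }
  items <- lapply(seq_len(nrow(reads)), function(i) {
    make_item(reads$id[[i]], reads$seq[[i]], reads$id[[i]])
  })
  n <- length(items)
  # ordered-pair merge cache: merge[[i]][[j]] appends item j to item i
  cache <- lapply(seq_len(n), function(i) {
    lapply(seq_len(n), function(j) {
      if (i == j) NULL else pair_merge(items[[i]], items[[j]], min_overlap, min_identity)
    })
  })
  while (length(items) > 1L) {
    n <- length(items)
    bi <- 0L
    bj <- 0L
    blen <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        m <- cache[[i]][[j]]
        if (m$len > blen ||
            (m$len == blen && blen > 0L &&
             paste(items[[i]]$id, items[[j]]$id) < paste(items[[bi]]$id, items[[bj]]$id))) {
          bi <- i; bj <- j; blen <- m$len
        }
      }
    }
    if (blen == 0L) break
    a <- items[[bi]]
    b <- items[[bj]]
    m <- cache[[bi]][[bj]]
    aseq <- if (m$aorient == "fwd") a$seq else a$rcseq
    bseq <- if (m$borient == "fwd") b$seq else b$rcseq
    merged_seq <- if (m$type == "contain") {
      aseq
    } else {
      paste0(aseq, substr(bseq, m$len + 1L, nchar(bseq)))
    }
    merged <- make_item(min(a$id, b$id), merged_seq, sort(c(a$members, b$members)))
    keep <- setdiff(seq_len(n), c(bi, bj))
    items <- c(items[keep], list(merged))
    cache <- lapply(cache[keep], function(row) row[keep])
    k <- length(items)
    for (i in seq_len(k - 1L)) {
      cache[[i]][[k]] <- pair_merge(items[[i]], merged, min_overlap, min_identity)
    }
    cache[[k]] <- lapply(seq_len(k), function(j) {
      if (j == k) NULL else pair_merge(merged, items[[j]], min_overlap, min_identity)
    })
  }
  ord <- order(vapply(items, `[[`, character(1), "id"))
  items <- items[ord]
  tibble(
    id = sprintf("contig_%03d", seq_along(items)),
    seq = vapply(items, `[[`, character(1), "seq"),
    n_reads = vapply(items, function(x) length(x$members), integer(1)),
    members = lapply(items, `[[`, "members")
  )
}

#' Map member reads back onto a contig consensus
#'
#' Locates each read (either orientation) in the consensus, allowing the
#' assembly mismatch budget, and returns per-base depth.
#'
#' @param contig One row of the [assemble_contigs()] result.
#' @param reads The read tibble the contig was assembled from.
#' @param min_identity Identity used during assembly (default 0.95).
#' @return A list with `offsets` (tibble `read`, `offset`, `strand`) and
#'   `depth` (integer vector along the consensus).
#' @export
contig_depth <- function(contig, reads, min_identity = 0.95) {
  cons <- Biostrings::DNAString(contig$seq[[1]])
  depth <- integer(nchar(contig$seq[[1]]))
  offs <- list()
  for (rid in contig$members[[1]]) {
    rseq <- reads$seq[[match(rid, reads$id)]]
    budget <- ceiling(nchar(rseq) * (1 - min_identity))
    hit <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") rseq else revcomp(rseq)
      m <- Biostrings::matchPattern(q, cons, max.mismatch = budget)
      if (length(m) > 0) {
        hit <- tibble(read = rid, offset = Biostrings::start(m)[[1]], strand = strand)
        break
      }
    }
    if (!is.null(hit)) {
      offs[[length(offs) + 1L]] <- hit
      span <- hit$offset:(hit$offset + nchar(rseq) - 1L)
      depth[span] <- depth[span] + 1L
    }
  }
  list(offsets = dplyr::bind_rows(offs), depth = depth)
}

#' Longest open reading frame across six frames
#'
#' @param nt Nucleotide sequence string.
#' @return One-row tibble `frame`, `protein` (longest stretch between stops,
#'   including M-initiated and 5'-truncated stretches).
#' @export
longest_orf <- function(nt) {
  frames <- translate_six_frames(nt)
  best <- tibble(frame = NA_integer_, protein = "")
  for (i in seq_len(nrow(frames))) {
    pieces <- strsplit(frames$protein[[i]], "*", fixed = TRUE)[[1]]
    if (length(pieces) == 0) next
    cand <- pieces[[which.max(nchar(pieces))]]
    if (nchar(cand) > nchar(best$protein)) {
      best <- tibble(frame = frames$frame[[i]], protein = cand)
    }
  }
  best
}

#' Validate a contig as a full-length Hsf candidate
#'
#' A contig is accepted iff (i) its longest ORF matches a reference protein
#' with P-value below `pvalue_max` (P approximated as `1 - exp(-E)` from the
#' Karlin-Altschul E-value) and (ii) the ORF carries both a detectable DBD
#' and an HR-A/B region.
#'
#' @param contig Contig sequence string (or one-row tibble).
#' @param refs Reference protein tibble.
#' @param pvalue_max Significance threshold (default 1e-4).
#' @param profile DBD profile for the structural check.
#' @param seed Seed for the DBD threshold calibration.
#' @return One-row tibble `accepted`, `reason`, `pvalue`, `orf_protein`.
#' @export
validate_full_length <- function(contig, refs, pvalue_max = 1e-4,
                                 profile = hsf_dbd_profile(), seed = 1) {
  if (is.data.frame(contig)) contig <- contig$seq[[1]]
  orf <- longest_orf(contig)
  if (nchar(orf$protein) < 50) {
    return(tibble(accepted = FALSE, reason = "no substantial ORF",
                  pvalue = NA_real_, orf_protein = orf$protein))
  }
  best_p <- Inf
  for (ri in seq_len(nrow(refs))) {
    al <- local_align(refs$seq[[ri]], orf$protein)
    if (al$score <= 0) next
    ev <- karlin_altschul_evalue(al$score, nchar(refs$seq[[ri]]), nchar(orf$protein))
    best_p <- min(best_p, 1 - exp(-ev))
  }
  if (!(best_p < pvalue_max)) {
    return(tibble(accepted = FALSE, reason = "no significant reference match",
                  pvalue = best_p, orf_protein = orf$protein))
  }
  dbd <- detect_dbd(orf$protein, profile = profile, seed = seed)
  if (nrow(dbd) == 0) {
    return(tibble(accepted = FALSE, reason = "missing DBD",
                  pvalue = best_p, orf_protein = orf$protein))
  }
  hr <- detect_hrab(orf$protein, dbd$end)
  if (nrow(hr) == 0) {
    return(tibble(accepted = FALSE, reason = "missing HR-A/B",
                  pvalue = best_p, orf_protein = orf$protein))
  }
  tibble(accepted = TRUE, reason = "full-length Hsf",
         pvalue = best_p, orf_protein = orf$protein)
}
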