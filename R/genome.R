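# Duplication calling, tandem clusters, spliced alignment and exon-intron
# structure bookkeeping.

#' Call duplicated gene pairs under the 80/80 rule
#'
#' Every unordered pair of coding sequences is aligned globally with free
#' end gaps. A pair is reported when the aligned region covers more than
#' `min_cov` of the longer gene and the identity over the aligned region
#' exceeds `min_sim`. Pairs on the same chromosome within the adjacency
#' window are typed `tandem`, all others `segmental`.
#'
#' @param cds Sequence tibble of coding sequences (`id`, `seq`).
#' @param loci Optional loci tibble (`gene_id`, `chromosome`, `start`) used
#'   for the tandem/segmental call; without it every pair is `segmental`.
#' @param min_cov,min_sim Rule thresholds (default 0.80/0.80, strict `>`).
#' @param tandem_window Maximum intervening family genes for a tandem call
#'   (default 5).
#' @return Tibble `gene_a`, `gene_b` (lexicographic), `coverage`,
#'   `similarity`, `type`.
#' @export
detect_duplications <- function(cds, loci = NULL, min_cov = 0.80, min_sim = 0.80,
                                tandem_window = 5) {
  n <- nrow(cds)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        st <- alignment_stats(cds$seq[[i]], cds$seq[[j]])
        if (st$coverage > min_cov && st$similarity > min_sim) {
          pair <- sort(c(cds$id[[i]], cds$id[[j]]))
          out[[length(out) + 1L]] <- tibble(
            gene_a = pair[[1]], gene_b = pair[[2]],
            coverage = st$coverage, similarity = st$similarity)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  coverage = numeric(0), similarity = numeric(0),
                  type = character(0)))
  }
  pairs <- dplyr::arrange(dplyr::bind_rows(out), .data$gene_a, .data$gene_b)
  pairs$type <- "segmental"
  if (!is.null(loci)) {
    ranks <- loci |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::mutate(rank = rank(.data$start, ties.method = "first")) |>
      dplyr::ungroup()
    for (k in seq_len(nrow(pairs))) {
      ra <- ranks[ranks$gene_id == pairs$gene_a[[k]], ]
      rb <- ranks[ranks$gene_id == pairs$gene_b[[k]], ]
      if (nrow(ra) == 1 && nrow(rb) == 1 &&
          ra$chromosome == rb$chromosome &&
          abs(ra$rank - rb$rank) - 1L <= tandem_window) {
        pairs$type[[k]] <- "tandem"
      }
    }
  }
  pairs
}

#' Coverage and similarity of a free-end-gap global alignment
#'
#' Helper behind the 80/80 duplication rule: coverage is the aligned length
#' divided by the longer sequence's length; similarity is the identity
#' fraction over the aligned columns (internal gaps count as differences).
#'
#' @param a,b Nucleotide sequence strings.
#' @return One-row tibble `coverage`, `similarity`, `aligned_length`.
#' @export
alignment_stats <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    type = "overlap")
  al_a <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  al_b <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  ncol_al <- length(al_a)
  matches <- sum(al_a == al_b & al_a != "-")
  tibble(coverage = ncol_al / max(nchar(a), nchar(b)),
         similarity = if (ncol_al > 0) matches / ncol_al else 0,
         aligned_length = ncol_al)
}

# ---- spliced alignment ----------------------------------------------------

lce <- function(chx, chg, x0, g0) {
  # longest common extension of chx[x0..] vs chg[g0..]
  nmax <- min(length(chx) - x0, length(chg) - g0) + 1L
  if (nmax <= 0L) return(0L)
  cmp <- chx[x0:(x0 + nmax - 1L)] != chg[g0:(g0 + nmax - 1L)]
  w <- which(cmp)
  if (length(w) == 0) nmax else w[[1]] - 1L
}

# donor/acceptor are the forward-strand intron boundary dinucleotides
# (GT/AG for plus-strand genes, CT/AC for minus-strand genes); NULL skips
# the dinucleotide constraint
splice_parse <- function(chx, chg, gseq, x0, g0, donor, acceptor, k = 20L,
                         min_intron = 30L, back_off = 12L, depth = 0L) {
  if (depth > 4L) return(NULL)
  e <- lce(chx, chg, x0, g0)
  if (x0 + e - 1L == length(chx)) {
    return(tibble(g_start = g0, g_end = g0 + e - 1L,
                  tx_start = x0, tx_end = x0 + e - 1L))
  }
  if (e < 1L) return(NULL)
  don <- if (is.null(donor)) NULL else seq_chars(donor)
  acc <- if (is.null(acceptor)) NULL else seq_chars(acceptor)
  for (b in seq(e, max(e - back_off, 1L))) {
    gi <- g0 + b # first intron base
    if (gi + 1L > length(chg)) next
    if (!is.null(don) && !(chg[[gi]] == don[[1]] && chg[[gi + 1L]] == don[[2]])) next
    nx <- x0 + b # next cds position to place
    if (nx + k - 1L > length(chx)) next
    chunk <- paste(chx[nx:(nx + k - 1L)], collapse = "")
    from <- gi + min_intron
    if (from > length(chg)) next
    hits <- Biostrings::start(Biostrings::matchPattern(
      chunk, Biostrings::subseq(gseq, from, length(chg)))) + from - 1L
    for (p in hits) {
      if (!is.null(acc) &&
          !(p >= 3L && chg[[p - 2L]] == acc[[1]] && chg[[p - 1L]] == acc[[2]])) next
      rest <- splice_parse(chx, chg, gseq, nx, p, donor, acceptor, k,
                           min_intron, back_off, depth + 1L)
      if (!is.null(rest)) {
        return(dplyr::bind_rows(
          tibble(g_start = g0, g_end = gi - 1L, tx_start = x0, tx_end = nx - 1L),
          rest))
      }
    }
  }
  NULL
}

#' Spliced alignment of a CDS to a genomic sequence
#'
#' Finds the exon chain that spells the CDS exactly, with introns required
#' to start GT and end AG; when no GT..AG chain exists the dinucleotide
#' constraint is dropped and the model is flagged (`gt_ag = FALSE`). Both
#' strands are tried; coordinates are 1-based inclusive on the forward
#' genomic strand.
#'
#' @param cds CDS string (or one-row sequence tibble).
#' @param genomic Genomic sequence string (or one-row tibble).
#' @param gene_id Id recorded in the model (default `"gene"`).
#' @return A gene-model tibble: one row per exon with `gene_id`, `exon`,
#'   `start`, `end` (genomic), `tx_start`, `tx_end` (transcript), `strand`,
#'   `gt_ag`.
#' @export
spliced_align <- function(cds, genomic, gene_id = "gene") {
  if (is.data.frame(cds)) cds <- cds$seq[[1]]
  if (is.data.frame(genomic)) genomic <- genomic$seq[[1]]
  cds <- toupper(cds)
  genomic <- toupper(genomic)
  gseq <- Biostrings::DNAString(genomic)
  chg <- seq_chars(genomic)
  k <- min(20L, nchar(cds))
  try_strand <- function(x, donor, acceptor) {
    chx <- seq_chars(x)
    anchor <- substr(x, 1L, k)
    starts <- Biostrings::start(Biostrings::matchPattern(anchor, gseq))
    for (s in starts) {
      res <- splice_parse(chx, chg, gseq, 1L, s, donor, acceptor, k)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (require_gtag in c(TRUE, FALSE)) {
    for (strand in c("+", "-")) {
      x <- if (strand == "+") cds else revcomp(cds)
      # on the forward strand a minus-strand gene's GT..AG intron reads CT..AC
      donor <- if (!require_gtag) NULL else if (strand == "+") "GT" else "CT"
      acceptor <- if (!require_gtag) NULL else if (strand == "+") "AG" else "AC"
      res <- try_strand(x, donor, acceptor)
      if (!is.null(res)) {
        res$gt_ag <- require_gtag
        if (strand == "-") {
          # transcript coordinates were computed on the reverse complement;
          # flip them back to the CDS frame
          L <- nchar(cds)
          res <- tibble(g_start = res$g_start, g_end = res$g_end,
                        tx_start = L - res$tx_end + 1L,
                        tx_end = L - res$tx_start + 1L, gt_ag = res$gt_ag)
        }
        res <- dplyr::arrange(res, .data$g_start)
        return(tibble(gene_id = gene_id, exon = seq_len(nrow(res)),
                      start = res$g_start, end = res$g_end,
                      tx_start = res$tx_start, tx_end = res$tx_end,
                      strand = strand, gt_ag = res$gt_ag))
      }
    }
  }
  abort("structure-not-found: CDS could not be spliced onto the genomic sequence")
}

#' Intron lengths of a gene model
#'
#' @param model Gene-model tibble from [spliced_align()] (one gene).
#' @return Tibble `intron`, `start`, `end`, `length`.
#' @export
model_introns <- function(model) {
  model <- dplyr::arrange(model, .data$start)
  if (nrow(model) < 2) {
    return(tibble(intron = integer(0), start = integer(0), end = integer(0),
                  length = integer(0)))
  }
  tibble(intron = seq_len(nrow(model) - 1L),
         start = model$end[-nrow(model)] + 1L,
         end = model$start[-1L] - 1L) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)
}

#' Histogram of intron counts across gene models
#'
#' @param models Gene-model tibble (one row per exon, any number of genes).
#' @return Tibble `n_introns`, `n_genes`.
#' @export
summarize_intron_counts <- function(models) {
  if (nrow(models) == 0) return(tibble(n_introns = integer(0), n_genes = integer(0)))
  models |>
    dplyr::count(.data$gene_id, name = "n_exons") |>
    dplyr::count(n_introns = .data$n_exons - 1L, name = "n_genes")
}

#' Check protein length implied by exon coordinates
#'
#' The implied protein length is `sum(exon lengths)/3 - 1` (the terminal
#' stop codon is removed). The check passes iff the exon total is divisible
#' by 3 and the implied length equals the given protein length.
#'
#' @param exon_lengths Integer vector of exon lengths (bp).
#' @param protein_length Expected protein length (residues).
#' @return One-row tibble `implied_length`, `pass`.
#' @export
check_length_consistency <- function(exon_lengths, protein_length) {
  total <- sum(exon_lengths)
  implied <- total / 3 - 1
  tibble(implied_length = implied,
         pass = total %% 3 == 0 && implied == protein_length)
}

#' Find tandem clusters of family genes
#'
#' With a whole-chromosome gene census, a cluster is a maximal run of family
#' genes separated by at most `window` intervening non-family genes. Without
#' a census, genes closer than `max_gap` bases (end to next start) on the
#' same chromosome are clustered.
#'
#' @param loci Family loci tibble (`gene_id`, `chromosome`, `start`, `end`).
#' @param window Maximum intervening non-family genes (default 5).
#' @param gene_census Optional tibble of all genes (`gene_id`, `chromosome`,
#'   `start`).
#' @param max_gap Distance threshold in bases when no census is given
#'   (default 10000).
#' @return Tibble `cluster`, `gene_id`, `chromosome`, `size` (clusters of
#'   size >= 2 only).
#' @export
find_tandem_clusters <- function(loci, window = 5, gene_census = NULL,
                                 max_gap = 10000) {
  out <- list()
  cluster_id <- 0L
  for (chr in unique(loci$chromosome)) {
    fam <- dplyr::arrange(loci[loci$chromosome == chr, , drop = FALSE], .data$start)
    if (nrow(fam) == 0) next
    if (!is.null(gene_census)) {
      census <- dplyr::arrange(
        gene_census[gene_census$chromosome == chr, , drop = FALSE], .data$start)
      pos <- match(fam$gene_id, census$gene_id)
      new_cluster <- c(TRUE, diff(pos) - 1L > window)
    } else {
      gap <- fam$start[-1L] - fam$end[-nrow(fam)]
      new_cluster <- c(TRUE, gap > max_gap)
    }
    grp <- cumsum(new_cluster)
    for (g in unique(grp)) {
      members <- fam$gene_id[grp == g]
      if (length(members) < 2) next
      cluster_id <- cluster_id + 1L
      out[[length(out) + 1L]] <- tibble(cluster = cluster_id, gene_id = members,
                                        chromosome = chr,
                                        size = length(members))
    }
  }
  if (length(out) == 0) {
    return(tibble(cluster = integer(0), gene_id = character(0),
                  chromosome = character(0), size = integer(0)))
  }
  dplyr::bind_rows(out)
}
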