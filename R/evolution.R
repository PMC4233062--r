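# Distances, neighbor-joining phylogeny with bootstrap, and Nei-Gojobori
# substitution statistics.

#' p-distance with pairwise deletion
#'
#' Proportion of differing sites over the columns where both sequences have
#' a residue; columns with a gap (`-`) or missing state (`X`/`N`/`?`) in
#' either sequence are excluded for the pair.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return One-row tibble `p`, `differences`, `sites`.
#' @export
p_distance_pairwise_deletion <- function(a, b) {
  cha <- seq_chars(toupper(a))
  chb <- seq_chars(toupper(b))
  if (length(cha) != length(chb)) abort("aligned sequences must have equal length")
  missing <- c("-", "X", "N", "?", ".")
  valid <- !(cha %in% missing) & !(chb %in% missing)
  sites <- sum(valid)
  if (sites == 0) return(tibble(p = NA_real_, differences = 0L, sites = 0L))
  diffs <- sum(cha[valid] != chb[valid])
  tibble(p = diffs / sites, differences = diffs, sites = sites)
}

#' Poisson multiple-hit correction
#'
#' `d = -ln(1 - p)`; undefined (flagged) for `p >= 1`.
#'
#' @param p p-distance in `[0, 1]`.
#' @return One-row tibble `d`, `undefined`.
#' @export
poisson_correct <- function(p) {
  if (is.na(p) || p >= 1) return(tibble(d = NA_real_, undefined = TRUE))
  tibble(d = -log(1 - p), undefined = FALSE)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param aln Tibble of aligned sequences (`id`, `seq`, equal lengths).
#' @param max_p Cap applied to p-distances at or beyond the Poisson-domain
#'   edge (p >= 1); capped pairs are counted in the `"n_capped"` attribute
#'   so saturation is flagged, not silently hidden.
#' @return A symmetric numeric matrix of Poisson-corrected distances
#'   (pairwise deletion), zero diagonal, attribute `n_capped`.
#' @export
dist_poisson <- function(aln, max_p = 0.999) {
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  n_capped <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pd <- p_distance_pairwise_deletion(aln$seq[[i]], aln$seq[[j]])
        p <- pd$p
        if (is.na(p) || p >= 1) {
          p <- max_p
          n_capped <- n_capped + 1L
        }
        D[i, j] <- D[j, i] <- poisson_correct(p)$d
      }
    }
  }
  attr(D, "n_capped") <- n_capped
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape) on the matrix with labels sorted
#' lexicographically beforehand, so ties resolve deterministically. Negative
#' branch lengths are clamped to zero and flagged.
#'
#' @param D Symmetric distance matrix with labels.
#' @return An object of class `hsf_nj`: a list with `tree` (ape `phylo`)
#'   and `n_clamped` (count of clamped negative branch lengths).
#' @export
build_nj <- function(D) {
  if (is.null(rownames(D))) stop("distance matrix must have labels")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  tree <- ape::nj(as.dist(D))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  structure(list(tree = tree, n_clamped = n_clamped), class = "hsf_nj")
}

#' @export
print.hsf_nj <- function(x, ...) {
  cat("Neighbor-joining tree:", length(x$tree$tip.label), "tips,",
      x$n_clamped, "negative branch length(s) clamped to 0\n")
  invisible(x)
}

#' Tidy the edge table of a neighbor-joining tree
#'
#' @param x `hsf_nj` object.
#' @param ... Unused.
#' @return Tibble `parent`, `child`, `length`, `tip`, `label`.
#' @export
tidy.hsf_nj <- function(x, ...) {
  tr <- x$tree
  n_tip <- length(tr$tip.label)
  tibble(parent = tr$edge[, 1], child = tr$edge[, 2],
         length = tr$edge.length,
         tip = tr$edge[, 2] <= n_tip,
         label = ifelse(tr$edge[, 2] <= n_tip, tr$tip.label[tr$edge[, 2]],
                        NA_character_))
}

#' One-row summary of a neighbor-joining tree
#'
#' @param x `hsf_nj` object.
#' @param ... Unused.
#' @return Tibble `n_tips`, `n_internal`, `total_length`, `n_clamped`.
#' @export
glance.hsf_nj <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label),
         n_internal = x$tree$Nnode,
         total_length = sum(x$tree$edge.length),
         n_clamped = x$n_clamped)
}

#' Generic tidiers
#' @param x Object to tidy or summarize.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write an `hsf_nj` tree as newick
#'
#' @param x `hsf_nj` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(x$tree, file = path)
  invisible(path)
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Columns are resampled with replacement `n_reps` times; each replicate
#' alignment yields a Poisson-corrected NJ tree, and support for each
#' internal edge of the reference tree is the fraction of replicate trees
#' containing the same bipartition.
#'
#' @param aln Tibble of aligned sequences (`id`, `seq`).
#' @param n_reps Number of replicates (must be >= 1; 1000 in the classical
#'   protocol).
#' @param seed Integer seed.
#' @return A list with `tree` (`hsf_nj` reference tree) and `support`
#'   (numeric vector, one entry per internal node in `ape` node order).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  ref <- build_nj(dist_poisson(aln))
  chs <- lapply(aln$seq, seq_chars)
  L <- length(chs[[1]])
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample(L, L, replace = TRUE)
      rep_aln <- tibble(id = aln$id,
                        seq = vapply(chs, function(ch) paste(ch[cols], collapse = ""),
                                     character(1)))
      build_nj(dist_poisson(rep_aln))$tree
    })
  })
  counts <- ape::prop.clades(ref$tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = ref, support = counts / n_reps)
}

# ---- Nei-Gojobori ---------------------------------------------------------

# fraction of the three single-nucleotide changes at each codon position
# that are synonymous; changes to stop codons count as non-synonymous
codon_syn_sites <- function(codon, gc) {
  aa <- gc[[codon]]
  if (is.na(aa) || aa == "*") return(NA_real_)
  s <- 0
  for (v in codon_variants(codon)) {
    if (gc[[v]] == aa) s <- s + 1 # stop variants are never synonymous
  }
  s / 3
}

# average synonymous/non-synonymous steps over all shortest mutational
# pathways between two codons, excluding paths through stop codons
codon_path_counts <- function(ca, cb, gc) {
  pos <- which(seq_chars(ca) != seq_chars(cb))
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(pos) else {
    if (d == 2) list(pos, rev(pos)) else {
      idx <- list()
      for (p in seq_len(6)) idx[[p]] <- pos[permutations3()[p, ]]
      idx
    }
  }
  tot_sd <- 0
  tot_nd <- 0
  n_valid <- 0
  chb <- seq_chars(cb)
  for (ordr in perms) {
    cur <- seq_chars(ca)
    sd_ <- 0
    nd_ <- 0
    ok <- TRUE
    for (p in ordr) {
      nxt <- cur
      nxt[[p]] <- chb[[p]]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") {
        ok <- FALSE
        break
      }
      if (aa_cur == aa_nxt) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    if (ok) {
      tot_sd <- tot_sd + sd_
      tot_nd <- tot_nd + nd_
      n_valid <- n_valid + 1
    }
  }
  if (n_valid == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = tot_sd / n_valid, nd = tot_nd / n_valid)
}

permutations3 <- function() {
  matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
         ncol = 3, byrow = TRUE)
}

#' Nei-Gojobori substitution counting for a CDS pair
#'
#' Unweighted-pathway counting: synonymous (S) and non-synonymous (N) site
#' totals are per-codon synonymous-change fractions averaged over both
#' sequences; observed differences are classified by averaging over all
#' shortest mutational pathways between differing codons, excluding paths
#' that cross a stop codon. Codons containing non-ACGT bases, terminal or
#' internal stops, or with no stop-free pathway are excluded from both
#' numerators and denominators.
#'
#' @param cds_a,cds_b In-frame CDS strings of equal length (divisible by 3).
#' @return One-row tibble `Sd`, `Nd`, `S`, `N`, `codons_compared`.
#' @export
count_substitutions_ng <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) abort("CDS pair must have equal length")
  if (nchar(cds_a) %% 3 != 0) abort("CDS length must be divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  n_codon <- nchar(cds_a) %/% 3
  idx <- 3 * seq_len(n_codon)
  cas <- toupper(substring(cds_a, idx - 2, idx))
  cbs <- toupper(substring(cds_b, idx - 2, idx))
  S <- 0
  Sd <- 0
  Nd <- 0
  used <- 0L
  for (k in seq_len(n_codon)) {
    ca <- cas[[k]]
    cb <- cbs[[k]]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    sa <- codon_syn_sites(ca, gc)
    sb <- codon_syn_sites(cb, gc)
    if (is.na(sa) || is.na(sb)) next
    pc <- codon_path_counts(ca, cb, gc)
    if (anyNA(pc)) next
    S <- S + (sa + sb) / 2 # codon_syn_sites already sums the per-position fractions
    Sd <- Sd + pc[["sd"]]
    Nd <- Nd + pc[["nd"]]
    used <- used + 1L
  }
  tibble(Sd = Sd, Nd = Nd, S = S, N = 3 * used - S, codons_compared = used)
}

#' Aggregate mutation frequencies over ortholog CDS pairs
#'
#' Total frequency is the summed pairwise-deletion differences over the
#' summed compared sites across all pairs; synonymous and non-synonymous
#' frequencies divide the summed Nei-Gojobori `Sd` and `Nd` by the same
#' shared site denominator, so `syn + nonsyn = total` by construction.
#'
#' @param pairs Tibble with columns `cds_a`, `cds_b` (one row per ortholog
#'   pair).
#' @return A list with `stats` (one-row tibble: `sites_compared`,
#'   `differences`, `total_freq`, `syn_freq`, `nonsyn_freq`) and `per_pair`
#'   (per-pair breakdown with `Sd`, `Nd`, `S`, `N`, `differences`, `sites`).
#' @export
mutation_frequency <- function(pairs) {
  per <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ng <- count_substitutions_ng(pairs$cds_a[[i]], pairs$cds_b[[i]])
    pd <- p_distance_pairwise_deletion(pairs$cds_a[[i]], pairs$cds_b[[i]])
    dplyr::bind_cols(tibble(pair = i), ng,
                     tibble(differences = pd$differences, sites = pd$sites))
  })
  sites <- sum(per$sites)
  stats <- tibble(
    sites_compared = sites,
    differences = sum(per$differences),
    total_freq = sum(per$differences) / sites,
    syn_freq = sum(per$Sd) / sites,
    nonsyn_freq = sum(per$Nd) / sites
  )
  list(stats = stats, per_pair = per)
}
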