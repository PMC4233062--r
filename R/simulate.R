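# Synthetic Hsf data with machine-readable planted truth.
#
# Every generator is deterministic given `seed`. Background regions use only
# polar residues (no L/I/V/M/F cores, no K/R) so the planted domains are the
# only instances of their signatures; the detectors are still exercised on
# realistic layouts because the planted elements follow the published Hsf
# architecture (DBD - linker - HR-A [insertion] HR-B - NLS [- AHA - NES]).

BG_POLAR <- c("S", "T", "N", "Q", "G", "A", "P", "H", "E", "D")
HEPTAD_X <- c("Q", "E", "A", "S", "N", "T", "D", "H", "G")
SPACER_AA <- c("Q", "E", "N", "S", "T", "G", "A", "H", "D")

LINKER_RANGE <- list(A = c(12L, 37L), B = c(16L, 77L), C = c(10L, 29L))
INSERTION_BY_CLASS <- c(A = 21L, B = 0L, C = 7L)

NLS_MOTIFS <- c("KKRR", "KKRRLK", "RKRR", "KKRKR", "KRRRR")
AHA_MOTIFS <- c("DVFWEQFLTE", "DEGFWEELLNE", "GFWERFLTEV", "DFWMEIDFVE")
NES_MOTIFS <- list(A = c("LTEQMGLL", "LVDQMGYL", "LTDQMGHL"),
                   B = c("LGLNLM", "LRLNLM"),
                   C = c("LGLNLM"))

rand_aa <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE), collapse = "")

subclass_consensus <- function(subclass, profile) {
  consensus <- seq_chars(attr(profile, "consensus"))
  # subclass signature: a reproducible set of consensus substitutions derived
  # from the subclass label, shared by all members of the subclass
  h <- sum(utf8ToInt(subclass) * seq_len(nchar(subclass)) * 131L) %% 100000L
  with_seed(h + 7L, {
    pos <- sample(length(consensus), 12L)
    consensus[pos] <- sample(setdiff(AA20, HYDROPHOBIC_CORE), 12L, replace = TRUE)
  })
  consensus
}

sample_dbd <- function(subclass, profile, noise = 0.08) {
  consensus <- subclass_consensus(subclass, profile)
  kinds <- unlist(lapply(DBD_LAYOUT, function(r) rep(r$kind, r$len)))
  out <- consensus
  flip <- runif(length(out)) < noise
  for (j in which(flip)) {
    out[[j]] <- sample(DBD_REGION_ALPHABET[[kinds[[j]]]], 1L)
  }
  paste(out, collapse = "")
}

heptad_block <- function() {
  x <- sample(HEPTAD_X, 15L, replace = TRUE)
  x[c(1L, 8L, 15L)] <- sample(c("L", "L", "L", "M", "F", "I", "V"), 3L, replace = TRUE)
  paste(x, collapse = "")
}

#' Generate one synthetic Hsf protein with planted truth
#'
#' The protein follows the canonical Hsf layout: a short N-terminal region, a
#' DBD sampled from the packaged consensus profile (with a reproducible
#' subclass signature), a class-specific linker (A: 12-37, B: 16-77,
#' C: 10-29 residues), two hydrophobic heptad blocks separated by the class
#' insertion (A: 21, B: 0, C: 7 residues), a basic NLS cluster and, for
#' class A, an AHA activator window plus a C-terminal NES.
#'
#' @param class `"A"`, `"B"` or `"C"`.
#' @param subclass Subclass template id (default `"<class>1"`); members of a
#'   subclass share a sequence signature so nearest-exemplar assignment has
#'   a recoverable target.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @param with_nes,with_aha Override the class defaults (class A: both TRUE).
#' @param profile DBD profile (default [hsf_dbd_profile()]).
#' @return A list with `protein` (one-row sequence tibble) and `truth`
#'   (one-row tibble of planted coordinates and labels).
#' @export
generate_hsf_protein <- function(class, subclass = paste0(class, "1"), seed = 1,
                                 id = paste0("syn", class, "_", seed),
                                 with_nes = (class == "A"),
                                 with_aha = (class == "A"),
                                 profile = hsf_dbd_profile()) {
  class <- match.arg(class, c("A", "B", "C"))
  with_seed(seed, {
    nterm <- rand_aa(sample(10:30, 1L), BG_POLAR)
    dbd <- sample_dbd(subclass, profile)
    lr <- LINKER_RANGE[[class]]
    # linker length follows the printed-table convention
    # (HR-A/B start - DBD end), i.e. residues between + 1
    linker_len <- sample(lr[[1]]:lr[[2]], 1L)
    linker <- rand_aa(linker_len - 1L, BG_POLAR)
    hra <- heptad_block()
    ins_len <- INSERTION_BY_CLASS[[class]]
    insertion <- if (ins_len > 0) rand_aa(ins_len, SPACER_AA) else ""
    hrb <- heptad_block()
    nls <- sample(NLS_MOTIFS, 1L)
    sp1 <- rand_aa(sample(8:20, 1L), BG_POLAR)
    aha <- if (with_aha) sample(AHA_MOTIFS, 1L) else ""
    sp2 <- if (with_aha) rand_aa(sample(8:20, 1L), BG_POLAR) else ""
    nes <- if (with_nes) sample(NES_MOTIFS[[class]], 1L) else ""
    sp3 <- if (with_nes) rand_aa(sample(4:10, 1L), BG_POLAR) else ""
    tailr <- rand_aa(sample(4:8, 1L), BG_POLAR)

    parts <- c(nterm, dbd, linker, hra, insertion, hrb, sp1, nls, sp2, aha,
               sp3, nes, tailr)
    offsets <- cumsum(c(0L, nchar(parts)))
    seqs <- paste(parts, collapse = "")
    at <- function(k) offsets[[k]] + 1L # start of part k
    dbd_start <- at(2L)
    dbd_end <- offsets[[3L]]
    hra_start <- at(4L)
    hra_end <- hra_start + 14L
    hrb_start <- at(6L)
    hrb_end <- hrb_start + 14L
    truth <- tibble(
      id = id, class = class, subclass = subclass, seed = seed,
      dbd_start = dbd_start, dbd_end = dbd_end,
      linker_length = linker_len,
      hra_start = hra_start, hra_end = hra_end,
      hrb_start = hrb_start, hrb_end = hrb_end,
      insertion = ins_len,
      nls_pos = at(8L),
      aha_pos = if (with_aha) at(10L) else NA_integer_,
      nes_pos = if (with_nes) at(12L) else NA_integer_,
      length = nchar(seqs)
    )
    list(protein = tibble(id = id, description = paste0("synthetic Hsf class ", class),
                          seq = seqs, moltype = "protein"),
         truth = truth)
  })
}

#' Generate a synthetic Hsf protein family
#'
#' Class composition defaults to the published cotton family (22 class A,
#' 15 class B, 3 class C); subclass templates cycle through A1-A9, B1-B5, C1.
#'
#' @param n_a,n_b,n_c Number of proteins per class.
#' @param seed Integer seed.
#' @return A list with `proteins` (sequence tibble) and `truth`.
#' @export
generate_hsf_family <- function(n_a = 22, n_b = 15, n_c = 3, seed = 1) {
  spec <- dplyr::bind_rows(
    tibble(class = rep("A", n_a),
           subclass = paste0("A", rep_len(1:9, n_a))),
    tibble(class = rep("B", n_b),
           subclass = paste0("B", rep_len(1:5, n_b))),
    tibble(class = rep("C", n_c),
           subclass = paste0("C", rep_len(1, n_c)))
  )
  res <- purrr::map(seq_len(nrow(spec)), function(i) {
    generate_hsf_protein(spec$class[[i]], spec$subclass[[i]],
                         seed = seed * 1000L + i,
                         id = sprintf("synHsf%d", i))
  })
  list(proteins = purrr::map_dfr(res, "protein"),
       truth = purrr::map_dfr(res, "truth"))
}

# ---- genomes --------------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_aa) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_aa - 1L, replace = TRUE), collapse = ""), "TAA")
}

random_dna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_copy <- function(seqs, identity, coverage) {
  len <- nchar(seqs)
  m <- max(30L, round(coverage * len))
  core <- seq_chars(substr(seqs, 1L, m))
  k <- round((1 - identity) * m)
  if (k > 0) {
    pos <- sample(m, k)
    for (p in pos) {
      core[[p]] <- sample(setdiff(c("A", "C", "G", "T"), core[[p]]), 1L)
    }
  }
  list(seq = paste(core, collapse = ""), n_sub = k, covered = m)
}

#' Generate a synthetic gene-family genome with planted duplications
#'
#' Genes are random coding sequences embedded in random genomic background
#' (default GC 0.35, plant-like) with one or two GT..AG introns each.
#' Duplicate copies are mutated to a requested identity over a requested
#' coverage of the source gene and always placed on a different chromosome
#' (segmental type); an optional tandem cluster places adjacent family genes
#' on one chromosome.
#'
#' @param n_genes Number of family genes.
#' @param n_chromosomes Number of chromosomes.
#' @param dup_pairs A list of `c(identity, coverage)` pairs (both in (0, 1]),
#'   one per planted duplication; pair `k` duplicates gene `2k-1` into gene
#'   `2k`.
#' @param tandem_cluster_size If > 0, this many non-duplicate genes are
#'   placed adjacently on one chromosome.
#' @param frac_two_introns Fraction of genes with two introns (default 0.05,
#'   i.e. 2 of 40); the rest get one intron.
#' @param seed Integer seed.
#' @return A list with `genome` (chromosome tibble), `loci` (gene loci),
#'   `cds` (spliced coding sequences) and `truth` (`genes`, `exons`,
#'   `dup_pairs`, `tandem`).
#' @export
generate_family_genome <- function(n_genes = 40, n_chromosomes = 13,
                                   dup_pairs = list(), tandem_cluster_size = 0,
                                   frac_two_introns = 0.05, seed = 1) {
  if (length(dup_pairs) > 0 && n_genes < 2) {
    abort("n_genes must be >= 2 when dup_pairs is non-empty")
  }
  for (dp in dup_pairs) {
    if (any(dp <= 0) || any(dp > 1)) {
      abort("duplication identity and coverage must lie in (0, 1]")
    }
  }
  if (2 * length(dup_pairs) + tandem_cluster_size > n_genes) {
    abort("not enough genes for the requested duplications and tandem cluster")
  }
  with_seed(seed, {
    ids <- sprintf("g%02d", seq_len(n_genes))
    cds <- character(n_genes)
    n_dup_genes <- 2L * length(dup_pairs)
    dup_truth <- tibble(gene_a = character(0), gene_b = character(0),
                        identity = numeric(0), coverage = numeric(0))
    for (i in seq_len(n_genes)) {
      if (length(dup_pairs) > 0 && i <= n_dup_genes && i %% 2L == 0L) next
      cds[[i]] <- random_cds(sample(250:450, 1L))
    }
    if (length(dup_pairs) > 0) {
      for (k in seq_along(dup_pairs)) {
        a <- 2L * k - 1L
        b <- 2L * k
        mc <- mutate_copy(cds[[a]], dup_pairs[[k]][[1]], dup_pairs[[k]][[2]])
        cds[[b]] <- mc$seq
        dup_truth <- dplyr::bind_rows(dup_truth, tibble(
          gene_a = ids[[a]], gene_b = ids[[b]],
          identity = dup_pairs[[k]][[1]], coverage = dup_pairs[[k]][[2]]))
      }
    }

    # chromosome assignment: duplicate partners on different chromosomes,
    # tandem genes adjacent on one chromosome
    chrom <- integer(n_genes)
    for (k in seq_along(dup_pairs)) {
      chrom[[2L * k - 1L]] <- ((2L * k - 2L) %% n_chromosomes) + 1L
      chrom[[2L * k]] <- ((2L * k - 1L) %% n_chromosomes) + 1L
    }
    free <- which(chrom == 0L)
    tandem_genes <- character(0)
    if (tandem_cluster_size > 0) {
      tandem_idx <- free[seq_len(tandem_cluster_size)]
      tandem_chrom <- ((n_chromosomes - 1L) %% n_chromosomes) + 1L
      chrom[tandem_idx] <- tandem_chrom
      tandem_genes <- ids[tandem_idx]
      free <- setdiff(free, tandem_idx)
    }
    chrom[free] <- (seq_along(free) - 1L) %% n_chromosomes + 1L

    n_two <- round(frac_two_introns * n_genes)
    two_intron <- sample(seq_len(n_genes), n_two)

    gene_tbl <- list()
    exon_tbl <- list()
    chrom_seq <- setNames(rep("", n_chromosomes), sprintf("chr%d", seq_len(n_chromosomes)))
    for (ci in seq_len(n_chromosomes)) {
      genes_here <- which(chrom == ci)
      # keep tandem genes adjacent, others in index order
      genes_here <- c(setdiff(genes_here, match(tandem_genes, ids)),
                      intersect(match(tandem_genes, ids), genes_here))
      pos <- nchar(chrom_seq[[ci]])
      prev_tandem <- FALSE
      for (gi in genes_here) {
        # tandem-cluster members sit a few hundred bases apart; everything
        # else is separated by tens of kilobases so only planted clusters
        # fall inside the tandem distance window
        in_tandem <- ids[[gi]] %in% tandem_genes
        spacer <- if (in_tandem && prev_tandem) {
          random_dna(sample(300:800, 1L))
        } else {
          random_dna(sample(15000:25000, 1L))
        }
        prev_tandem <- in_tandem
        n_introns <- if (gi %in% two_intron) 2L else 1L
        g <- build_gene_cassette(cds[[gi]], n_introns)
        strand <- sample(c("+", "-"), 1L)
        cassette <- g$cassette
        exons <- g$exons # forward cassette coords
        if (strand == "-") {
          cassette <- revcomp(cassette)
          L <- nchar(cassette)
          exons <- tibble(start = L - g$exons$end + 1L, end = L - g$exons$start + 1L,
                          tx_start = g$exons$tx_start, tx_end = g$exons$tx_end)
          exons <- exons[rev(seq_len(nrow(exons))), ]
        }
        offset <- pos + nchar(spacer)
        chrom_seq[[ci]] <- paste0(chrom_seq[[ci]], spacer, cassette)
        pos <- nchar(chrom_seq[[ci]])
        gene_tbl[[length(gene_tbl) + 1L]] <- tibble(
          gene_id = ids[[gi]], chromosome = names(chrom_seq)[[ci]],
          start = offset + 1L, end = offset + nchar(cassette),
          strand = strand, n_introns = n_introns)
        exon_tbl[[length(exon_tbl) + 1L]] <- tibble(
          gene_id = ids[[gi]], exon = seq_len(nrow(exons)),
          start = offset + exons$start, end = offset + exons$end,
          tx_start = exons$tx_start, tx_end = exons$tx_end, strand = strand)
      }
      chrom_seq[[ci]] <- paste0(chrom_seq[[ci]], random_dna(sample(400:1200, 1L)))
    }
    loci <- dplyr::bind_rows(gene_tbl)
    list(
      genome = tibble(chromosome = names(chrom_seq), seq = unname(chrom_seq),
                      moltype = "dna"),
      loci = loci[, c("gene_id", "chromosome", "start", "end", "strand")],
      cds = tibble(id = ids, description = "", seq = cds, moltype = "dna"),
      truth = list(genes = loci, exons = dplyr::bind_rows(exon_tbl),
                   dup_pairs = dup_truth, tandem = tandem_genes)
    )
  })
}

# split a CDS into exons with GT..AG introns; returns cassette coordinates
build_gene_cassette <- function(cds, n_introns) {
  len <- nchar(cds)
  cuts <- sort(sample(seq(60L, len - 60L), n_introns))
  # enforce distinct, well-separated cut points
  while (n_introns == 2L && diff(cuts) < 60L) {
    cuts <- sort(sample(seq(60L, len - 60L), n_introns))
  }
  bounds <- c(0L, cuts, len)
  exon_seqs <- character(n_introns + 1L)
  for (e in seq_len(n_introns + 1L)) {
    exon_seqs[[e]] <- substr(cds, bounds[[e]] + 1L, bounds[[e + 1L]])
  }
  introns <- vapply(seq_len(n_introns), function(i) {
    paste0("GT", random_dna(sample(60L:300L, 1L)), "AG")
  }, character(1))
  cassette <- exon_seqs[[1]]
  exons <- tibble(start = 1L, end = nchar(exon_seqs[[1]]),
                  tx_start = 1L, tx_end = nchar(exon_seqs[[1]]))
  for (i in seq_len(n_introns)) {
    cassette <- paste0(cassette, introns[[i]], exon_seqs[[i + 1L]])
    g_start <- nchar(cassette) - nchar(exon_seqs[[i + 1L]]) + 1L
    exons <- dplyr::bind_rows(exons, tibble(
      start = g_start, end = nchar(cassette),
      tx_start = exons$tx_end[i] + 1L,
      tx_end = exons$tx_end[i] + nchar(exon_seqs[[i + 1L]])))
  }
  list(cassette = cassette, exons = exons)
}

# ---- ESTs -----------------------------------------------------------------

#' Generate synthetic EST reads from a coding sequence
#'
#' Reads are substrings of the CDS (or its reverse complement; both strands
#' are emitted) with iid substitution errors.
#'
#' @param cds CDS string (or one-row sequence tibble).
#' @param coverage Mean reads per base (0 gives an empty read set).
#' @param read_len Read length (must not exceed the CDS length).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A tibble of reads with planted-truth columns `source_start`,
#'   `strand`, `n_errors`.
#' @export
generate_ests <- function(cds, coverage = 10, read_len = 100, error_rate = 0,
                          seed = 1) {
  if (is.data.frame(cds)) cds <- cds$seq[[1]]
  len <- nchar(cds)
  if (read_len > len) abort("read_len must not exceed the CDS length")
  n_reads <- round(coverage * len / read_len)
  empty <- tibble(id = character(0), description = character(0),
                  seq = character(0), moltype = character(0),
                  source_start = integer(0), strand = character(0),
                  n_errors = integer(0))
  if (n_reads < 1L) return(empty)
  with_seed(seed, {
    # evenly spaced starts tile the whole CDS (both ends included), so at
    # coverage >= 2 consecutive reads overlap by read_len - spacing
    starts <- as.integer(round(seq(1L, len - read_len + 1L, length.out = n_reads)))
    strands <- rep_len(c("+", "-"), n_reads)
    reads <- vapply(seq_len(n_reads), function(i) {
      substr(cds, starts[[i]], starts[[i]] + read_len - 1L)
    }, character(1))
    n_err <- integer(n_reads)
    if (error_rate > 0) {
      for (i in seq_len(n_reads)) {
        ch <- seq_chars(reads[[i]])
        flip <- which(runif(read_len) < error_rate)
        for (p in flip) ch[[p]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[p]]), 1L)
        n_err[[i]] <- length(flip)
        reads[[i]] <- paste(ch, collapse = "")
      }
    }
    minus <- strands == "-"
    reads[minus] <- vapply(reads[minus], revcomp, character(1), USE.NAMES = FALSE)
    tibble(id = sprintf("est_%04d", seq_len(n_reads)), description = "",
           seq = reads, moltype = "dna", source_start = starts,
           strand = strands, n_errors = n_err)
  })
}

# ---- ortholog pairs -------------------------------------------------------

codon_variants <- function(codon) {
  ch <- seq_chars(codon)
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[[p]])) {
      v <- ch
      v[[p]] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Generate an ortholog CDS pair with planted substitution counts
#'
#' The partner sequence differs from the input by exactly `n_syn` synonymous
#' and `n_nonsyn` non-synonymous single-nucleotide changes, each in a
#' distinct codon (single mutational path), verified against the standard
#' codon table during generation. Stop codons are never created.
#'
#' @param cds CDS string (length divisible by 3, no internal stops).
#' @param n_syn,n_nonsyn Planted change counts.
#' @param seed Integer seed.
#' @return A list with `cds_a`, `cds_b` and `truth`.
#' @export
generate_ortholog_pair <- function(cds, n_syn, n_nonsyn, seed = 1) {
  if (is.data.frame(cds)) cds <- cds$seq[[1]]
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  n_codon <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  with_seed(seed, {
    usable <- setdiff(seq_len(n_codon), c(1L, n_codon)) # keep start/stop intact
    order_try <- sample(usable)
    used <- integer(0)
    place <- function(n_changes, synonymous) {
      placed <- 0L
      for (ci in order_try) {
        if (placed >= n_changes) break
        if (ci %in% used) next
        from <- codons[[ci]]
        vars <- codon_variants(from)
        ok <- vars[vapply(vars, function(v) {
          gc[[v]] != "*" && ((gc[[v]] == gc[[from]]) == synonymous)
        }, logical(1))]
        if (length(ok) == 0) next
        codons[[ci]] <<- sample(ok, 1L)
        used <<- c(used, ci)
        placed <- placed + 1L
      }
      if (placed < n_changes) {
        abort("could not place all requested substitutions; CDS too short")
      }
    }
    place(n_syn, synonymous = TRUE)
    place(n_nonsyn, synonymous = FALSE)
    list(cds_a = cds, cds_b = paste(codons, collapse = ""),
         truth = tibble(n_syn = n_syn, n_nonsyn = n_nonsyn))
  })
}

# ---- Ct tables ------------------------------------------------------------

HEAT_SAMPLES <- c("CK", "1h", "2h", "4h")

default_fold_trajectories <- function() {
  list(
    unchanged    = c(`1h` = 1,    `2h` = 1,   `4h` = 1),
    inhibited    = c(`1h` = 0.25, `2h` = 0.3, `4h` = 0.4),
    immediate_up = c(`1h` = 50,   `2h` = 10,  `4h` = 3),
    late_up      = c(`1h` = 0.4,  `2h` = 1.5, `4h` = 4)
  )
}

#' Generate a qPCR Ct table with planted heat-shock response patterns
#'
#' The reference gene holds a constant Ct across samples (up to noise);
#' each target gene's Ct is shifted by `-log2(fold)` at the treated/recovery
#' timepoints according to its planted pattern, so the comparative
#' delta-delta-CT fold-changes invert the construction exactly at zero
#' noise.
#'
#' @param patterns Tibble with columns `gene`, `pattern` (one of `unchanged`,
#'   `inhibited`, `immediate_up`, `late_up`) and optionally `fold_1h` to
#'   override the 1 h fold of the default trajectory for that gene (the
#'   2 h/4 h folds are scaled proportionally for up-regulated genes).
#' @param fold_params Named list of fold trajectories per pattern (defaults
#'   from `default_fold_trajectories()`).
#' @param n_reps Technical replicates per cell (default 4).
#' @param noise_sd SD of Gaussian Ct noise (default 0.15 cycles).
#' @param reference Reference gene id (default `"UBQ"`).
#' @param seed Integer seed.
#' @return A list with `ct` (long Ct tibble including the reference gene)
#'   and `truth` (gene, pattern, planted folds).
#' @export
generate_ct_table <- function(patterns, fold_params = default_fold_trajectories(),
                              n_reps = 4, noise_sd = 0.15, reference = "UBQ",
                              seed = 1) {
  stopifnot(all(c("gene", "pattern") %in% names(patterns)))
  bad <- setdiff(unique(patterns$pattern), names(fold_params))
  if (length(bad) > 0) abort(paste0("unknown pattern(s): ", paste(bad, collapse = ", ")))
  ref_ct <- 15
  base_ct <- 22
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(patterns))) {
      g <- patterns$gene[[i]]
      pat <- patterns$pattern[[i]]
      folds <- fold_params[[pat]]
      if ("fold_1h" %in% names(patterns) && !is.na(patterns$fold_1h[[i]])) {
        folds <- folds * patterns$fold_1h[[i]] / folds[["1h"]]
      }
      folds <- c(CK = 1, folds)
      for (s in HEAT_SAMPLES) {
        ct_mean <- base_ct - log2(folds[[s]])
        rows[[length(rows) + 1L]] <- tibble(
          gene = g, sample = s, replicate = as.character(seq_len(n_reps)),
          ct = ct_mean + rnorm(n_reps, 0, noise_sd))
      }
      truth[[length(truth) + 1L]] <- tibble(
        gene = g, pattern = pat,
        fold_1h = folds[["1h"]], fold_2h = folds[["2h"]], fold_4h = folds[["4h"]])
    }
    for (s in HEAT_SAMPLES) {
      rows[[length(rows) + 1L]] <- tibble(
        gene = reference, sample = s, replicate = as.character(seq_len(n_reps)),
        ct = ref_ct + rnorm(n_reps, 0, noise_sd))
    }
    list(ct = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
}

#' Default heat-shock pattern assignment for a 40-gene family
#'
#' Reproduces the published pattern mix: 5 unchanged, 11 inhibited, 8
#' immediately up-regulated (the strongest at 400-fold after 1 h) and 16
#' late up-regulated genes.
#'
#' @param prefix Gene-name prefix (default `"synHsf"`).
#' @return A patterns tibble suitable for [generate_ct_table()].
#' @export
default_heat_patterns <- function(prefix = "synHsf") {
  imm_folds <- c(400, 100, 50, 30, 20, 15, 12, 10)
  tibble(
    gene = paste0(prefix, 1:40),
    pattern = c(rep("unchanged", 5), rep("inhibited", 11),
                rep("immediate_up", 8), rep("late_up", 16)),
    fold_1h = c(rep(NA, 16), imm_folds, rep(NA, 16))
  )
}

#' Generate WT vs mutant Ct tables across fiber-development stages
#'
#' Stages are days post anthesis (-3, -1, 0, +3 DPA). Differential genes are
#' expressed `ratio`-fold higher in the WT at every stage; all other genes
#' are equal in the two genotypes up to noise.
#'
#' @param n_genes Number of genes.
#' @param differential Integer indices of WT-elevated genes.
#' @param ratio WT/mutant expression ratio for the differential genes
#'   (scalar, or one value per entry of `differential`).
#' @param n_reps,noise_sd,seed As in [generate_ct_table()].
#' @param prefix Gene-name prefix.
#' @return A list with `ct_wt`, `ct_mut` (long Ct tibbles) and `truth`.
#' @export
generate_genotype_ct <- function(n_genes = 40, differential = integer(0),
                                 ratio = 6, n_reps = 4, noise_sd = 0.15,
                                 seed = 1, prefix = "synHsf") {
  stages <- c("-3DPA", "-1DPA", "0DPA", "+3DPA")
  ref_ct <- 15
  base_ct <- 22
  genes <- paste0(prefix, seq_len(n_genes))
  ratios <- setNames(rep(1, n_genes), genes)
  ratios[differential] <- rep_len(ratio, length(differential))
  with_seed(seed, {
    mk <- function(shifted) {
      rows <- list()
      for (g in genes) {
        ct_mean <- base_ct - if (shifted) log2(ratios[[g]]) else 0
        for (s in stages) {
          rows[[length(rows) + 1L]] <- tibble(
            gene = g, sample = s, replicate = as.character(seq_len(n_reps)),
            ct = ct_mean + rnorm(n_reps, 0, noise_sd))
        }
      }
      for (s in stages) {
        rows[[length(rows) + 1L]] <- tibble(
          gene = "UBQ", sample = s, replicate = as.character(seq_len(n_reps)),
          ct = ref_ct + rnorm(n_reps, 0, noise_sd))
      }
      dplyr::bind_rows(rows)
    }
    list(ct_wt = mk(TRUE), ct_mut = mk(FALSE),
         truth = tibble(gene = genes, differential = unname(ratios) != 1,
                        ratio = unname(ratios)))
  })
}
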