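#' Read a FASTA file into a sequence tibble
#'
#' Sequences are returned one row per record with the header split into `id`
#' (first whitespace-delimited token) and `description` (remainder).
#' Sequence characters are upper-cased and validated against the declared
#' alphabet; record ids must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"dna"`, `"protein"`, or `"auto"` (default) to guess from
#'   residue composition.
#' @return A tibble with columns `id`, `description`, `seq`, `moltype`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "ACGT", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, moltype = c("auto", "dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  descs <- character()
  seqs <- character()
  cur <- NULL
  cur_line <- 0L
  flush <- function() {
    if (is.null(cur)) return(invisible())
    if (!nzchar(cur$seq)) {
      abort(sprintf("FASTA format error at line %d: record '%s' has an empty sequence",
                    cur$line, cur$id))
    }
    ids <<- c(ids, cur$id)
    descs <<- c(descs, cur$desc)
    seqs <<- c(seqs, cur$seq)
    invisible()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) {
        abort(sprintf("FASTA format error at line %d: malformed header '%s'", i, ln))
      }
      desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
      cur <- list(id = id, desc = desc, seq = "", line = i)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) {
        abort(sprintf("FASTA format error at line %d: sequence data before first header", i))
      }
      cur$seq <- paste0(cur$seq, gsub("\\s", "", ln))
    }
  }
  flush()
  if (length(ids) == 0L) abort(paste0("FASTA format error: no records in ", path))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  if (moltype == "auto") {
    dna_frac <- mean(vapply(seqs, function(s) {
      ch <- seq_chars(s)
      mean(ch %in% c("A", "C", "G", "T", "U", "N"))
    }, numeric(1)))
    moltype <- if (dna_frac > 0.9) "dna" else "protein"
  }
  allowed <- if (moltype == "dna") {
    c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")
  } else {
    c(AA20, "X", "B", "Z", "J", "U", "O", "*", "-")
  }
  for (k in seq_along(seqs)) {
    bad <- setdiff(unique(seq_chars(seqs[[k]])), allowed)
    if (length(bad) > 0L) {
      abort(sprintf("record '%s' contains characters outside the %s alphabet: %s",
                    ids[[k]], moltype, paste(bad, collapse = "")))
    }
  }
  tibble(id = ids, description = descs, seq = seqs, moltype = moltype)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else rep("", nrow(seqs))
  out <- character()
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(desc[[i]])) paste(seqs$id[[i]], desc[[i]]) else seqs$id[[i]]
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs$seq[[i]])
    out <- c(out, paste0(">", hdr), strsplit(body, "\n", fixed = TRUE)[[1]])
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene-level loci from a GFF3 file
#'
#' Only `gene` features are returned; mRNA/exon/CDS lines are ignored at this
#' level. Coordinates are kept 1-based inclusive exactly as in the file.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_gene_loci <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gff <- readr::read_tsv(
    path,
    comment = "#",
    col_names = c("seqid", "source", "type", "start", "end",
                  "score", "strand", "phase", "attributes"),
    col_types = readr::cols(
      seqid = readr::col_character(), source = readr::col_character(),
      type = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), score = readr::col_character(),
      strand = readr::col_character(), phase = readr::col_character(),
      attributes = readr::col_character()
    ),
    progress = FALSE
  )
  genes <- dplyr::filter(gff, .data$type == "gene")
  if (nrow(genes) > 0 && any(genes$end < genes$start)) {
    bad <- genes[genes$end < genes$start, ]
    abort(sprintf("GFF3 format error: end < start for feature at %s:%d-%d",
                  bad$seqid[[1]], bad$start[[1]], bad$end[[1]]))
  }
  ids <- stringr::str_match(genes$attributes, "ID=([^;]+)")[, 2]
  if (anyNA(ids)) abort("GFF3 format error: gene feature without an ID attribute")
  tibble(
    gene_id = ids,
    chromosome = genes$seqid,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = genes$strand
  )
}

#' Write gene loci as a minimal GFF3 file
#'
#' @param loci Tibble with `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_gene_loci <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\thsfkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$chromosome, loci$start, loci$end, loci$strand, loci$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicate-resolved qPCR Ct table
#'
#' The input is a TSV with columns `gene`, `sample`, `replicate`, `ct`
#' (one row per technical replicate).
#'
#' @param path Path to the TSV.
#' @return A long tibble with the four required columns, `ct` numeric.
#' @seealso [ct_summary()] for the per-cell replicate summary.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Ct table not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("gene", "sample", "replicate", "ct")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("Ct table is missing required column(s): ",
                 paste(missing, collapse = ", "),
                 " (required header: gene, sample, replicate, ct)"))
  }
  ct <- suppressWarnings(as.numeric(tab$ct))
  if (anyNA(ct) && !anyNA(tab$ct)) {
    bad <- tab$ct[is.na(ct)][[1]]
    abort(paste0("non-numeric Ct value: '", bad, "'"))
  }
  tibble(gene = tab$gene, sample = tab$sample,
         replicate = tab$replicate, ct = ct)
}

#' Summarize a Ct table per gene x sample cell
#'
#' Reports the replicate count, mean and SD of Ct for every gene x sample
#' combination; combinations absent from the table are flagged as missing.
#'
#' @param ct Long Ct tibble as returned by [read_ct_table()].
#' @return A tibble with `gene`, `sample`, `n_reps`, `ct_mean`, `ct_sd`,
#'   `missing`.
#' @export
ct_summary <- function(ct) {
  cells <- ct |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     ct_mean = mean(.data$ct),
                     ct_sd = sd(.data$ct),
                     .groups = "drop")
  grid <- tidyr::expand_grid(gene = unique(ct$gene), sample = unique(ct$sample))
  grid |>
    dplyr::left_join(cells, by = c("gene", "sample")) |>
    dplyr::mutate(n_reps = dplyr::coalesce(.data$n_reps, 0L),
                  missing = .data$n_reps == 0L)
}
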