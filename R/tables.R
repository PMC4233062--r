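#' Published reference tables for the cotton Hsf family
#'
#' Three tables transcribed from the original genome-wide survey of the
#' Upland cotton (D-subgenome) Hsf family ship with the package as plain
#' TSV fixtures:
#'
#' * `gh_table1()` — gene names, *G. raimondii* locus ids, protein length,
#'   isoelectric point, molecular weight, chromosome.
#' * `gh_table2()` — domain architecture: class/subclass label, DBD
#'   coordinates, printed linker length, HR-A/B coordinates, NLS/NES/AHA
#'   motifs. `dbd_len_text` carries the DBD length stated in the survey's
#'   narrative where it differs from (or confirms) the printed coordinates.
#' * `gh_table3()` — transcript-relative exon coordinates and intron lengths.
#'
#' @return A tibble (40 rows each).
#' @name gh_tables
NULL

#' @rdname gh_tables
#' @export
gh_table1 <- function() {
  readr::read_tsv(hsf_extdata("gh_table1.tsv"),
                  col_types = "ccdddc", progress = FALSE)
}

#' @rdname gh_tables
#' @export
gh_table2 <- function() {
  tab <- readr::read_tsv(hsf_extdata("gh_table2.tsv"),
                         col_types = "ccciiiccccc", progress = FALSE)
  hr <- stringr::str_match(tab$hrab, "^(\\d+)-(\\d+)")
  tab$hrab_start <- as.integer(hr[, 2])
  tab$hrab_end <- as.integer(hr[, 3])
  tab$dbd_len_text <- suppressWarnings(as.integer(tab$dbd_len_text))
  tab
}

#' @rdname gh_tables
#' @export
gh_table3 <- function() {
  readr::read_tsv(hsf_extdata("gh_table3.tsv"),
                  col_types = "cciiiiiiii", progress = FALSE)
}

#' Parse the leading class letter from a subclass label
#'
#' `"A1a"` gives `"A"`, `"B4e"` gives `"B"`; anything not starting with
#' A, B or C gives `NA`.
#'
#' @param subclass Character vector of subclass labels.
#' @return Character vector of class letters.
#' @export
parse_class <- function(subclass) {
  cls <- substr(subclass, 1, 1)
  ifelse(cls %in% c("A", "B", "C"), cls, NA_character_)
}

#' Consistency report for the published domain and structure tables
#'
#' Recomputes every internally checkable quantity in the packaged tables and
#' reports each disagreement instead of silently correcting it:
#'
#' * linker length vs `HR-A/B start - DBD end` (the convention under which
#'   most printed rows reproduce exactly);
#' * DBD length from coordinates vs the narrative length where one is stated;
#' * protein length implied by the exon coordinates
#'   (`sum(exon lengths)/3 - 1`, terminal stop removed) vs the printed
#'   protein length.
#'
#' @return A tibble with columns `gene`, `check`, `expected`, `observed`
#'   (one row per failed check).
#' @export
check_table_consistency <- function() {
  t1 <- gh_table1()
  t2 <- gh_table2()
  t3 <- gh_table3()
  out <- list()

  linker_coord <- t2$hrab_start - t2$dbd_end
  bad <- which(linker_coord != t2$linker)
  if (length(bad) > 0) {
    out$linker <- tibble(gene = t2$gene[bad], check = "linker_vs_coordinates",
                         expected = as.numeric(t2$linker[bad]),
                         observed = as.numeric(linker_coord[bad]))
  }

  dbd_len <- t2$dbd_end - t2$dbd_start + 1L
  has_text <- !is.na(t2$dbd_len_text)
  bad <- which(has_text & dbd_len != t2$dbd_len_text)
  if (length(bad) > 0) {
    out$dbd <- tibble(gene = t2$gene[bad], check = "dbd_length_vs_text",
                      expected = as.numeric(t2$dbd_len_text[bad]),
                      observed = as.numeric(dbd_len[bad]))
  }

  cross <- dplyr::inner_join(t3, t1[, c("gene", "aa")], by = "gene")
  exon_total <- (cross$exon1_end - cross$exon1_start + 1L) +
    (cross$exon2_end - cross$exon2_start + 1L) +
    dplyr::coalesce(cross$exon3_end - cross$exon3_start + 1L, 0L)
  implied <- exon_total / 3 - 1
  bad <- which(implied != cross$aa)
  if (length(bad) > 0) {
    out$len <- tibble(gene = cross$gene[bad], check = "implied_protein_length",
                      expected = as.numeric(cross$aa[bad]),
                      observed = implied[bad])
  }
  dplyr::bind_rows(out)
}
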