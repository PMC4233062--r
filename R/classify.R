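# Class/subclass assignment and chromosome-ordered gene naming.

#' Assign the Hsf class from the HR-A/B insertion length
#'
#' The insertion between the HR-A and HR-B heptad blocks is the class
#' signature: 21 residues for class A, none for class B, 7 for class C.
#' Values are snapped within +/-2 of a signature; anything else is left
#' unclassified with the raw value surfaced as evidence.
#'
#' @param insertion_raw Integer vector of raw insertion lengths (residues
#'   strictly between the HR-A and HR-B cores).
#' @return Tibble with `class` (`"A"`, `"B"`, `"C"` or `NA`) and
#'   `insertion_raw`.
#' @export
assign_class <- function(insertion_raw) {
  sigs <- c(A = 21L, B = 0L, C = 7L)
  cls <- vapply(insertion_raw, function(r) {
    if (is.na(r)) return(NA_character_)
    d <- abs(sigs - r)
    if (min(d) > 2L) NA_character_ else names(sigs)[[which.min(d)]]
  }, character(1))
  tibble(class = cls, insertion_raw = insertion_raw)
}

#' Poisson-corrected distance between two domain region strings
#'
#' Globally aligns the two regions (BLOSUM62, affine gaps), computes the
#' p-distance under pairwise deletion and applies the Poisson correction.
#' @noRd
domain_distance <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  pd <- p_distance_pairwise_deletion(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
  pc <- poisson_correct(pd$p)
  if (pc$undefined) Inf else pc$d
}

#' Assign the subclass by nearest labeled exemplar
#'
#' The query's concatenated DBD + HR-A/B region is compared with each
#' exemplar of its class by Poisson-corrected distance over a global
#' alignment; the nearest exemplar donates its subclass label (ties broken
#' by lexicographic exemplar id). With no exemplar of the class, only the
#' class letter is returned.
#'
#' @param query_region Concatenated DBD+HR-A/B string of the query.
#' @param query_class Class letter of the query.
#' @param exemplars Tibble with `id`, `subclass`, `region` (same
#'   concatenated representation) for the labeled references.
#' @return One-row tibble `subclass`, `exemplar`, `distance`.
#' @export
assign_subclass <- function(query_region, query_class, exemplars) {
  pool <- exemplars[parse_class(exemplars$subclass) == query_class, , drop = FALSE]
  if (nrow(pool) == 0) {
    return(tibble(subclass = query_class, exemplar = NA_character_,
                  distance = NA_real_))
  }
  d <- vapply(pool$region, function(r) domain_distance(query_region, r),
              numeric(1), USE.NAMES = FALSE)
  ord <- order(d, pool$id)
  best <- ord[[1]]
  tibble(subclass = pool$subclass[[best]], exemplar = pool$id[[best]],
         distance = d[[best]])
}

#' Classify annotated proteins into classes and subclasses
#'
#' @param annotation Annotation tibble from [annotate_hsf()].
#' @param proteins Sequence tibble matching the annotation ids.
#' @param exemplars Optional exemplar tibble for subclass assignment (see
#'   [assign_subclass()]); without it only classes are assigned.
#' @return The annotation tibble with `class`, `subclass`, `exemplar`,
#'   `distance` columns appended.
#' @export
classify_hsf <- function(annotation, proteins = NULL, exemplars = NULL) {
  out <- dplyr::bind_cols(annotation,
                          assign_class(annotation$insertion_raw)["class"])
  if (is.null(exemplars)) {
    out$subclass <- out$class
    return(out)
  }
  stopifnot(!is.null(proteins))
  sub <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
    if (is.na(out$class[[i]]) || is.na(out$dbd_start[[i]]) ||
        is.na(out$hrb_end[[i]])) {
      return(tibble(subclass = NA_character_, exemplar = NA_character_,
                    distance = NA_real_))
    }
    s <- proteins$seq[[match(out$id[[i]], proteins$id)]]
    region <- paste0(substr(s, out$dbd_start[[i]], out$dbd_end[[i]]),
                     substr(s, out$hra_start[[i]], out$hrb_end[[i]]))
    assign_subclass(region, out$class[[i]], exemplars)
  })
  dplyr::bind_cols(out, sub)
}

#' Extract the concatenated DBD+HR-A/B region for exemplar construction
#'
#' @param proteins Sequence tibble.
#' @param annotation Matching annotation tibble.
#' @return Tibble `id`, `region`.
#' @export
domain_region <- function(proteins, annotation) {
  purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    s <- proteins$seq[[match(annotation$id[[i]], proteins$id)]]
    tibble(id = annotation$id[[i]],
           region = paste0(
             substr(s, annotation$dbd_start[[i]], annotation$dbd_end[[i]]),
             substr(s, annotation$hra_start[[i]], annotation$hrb_end[[i]])))
  })
}

#' Name genes by chromosomal order
#'
#' Genes are sorted by natural chromosome order, then start coordinate (or
#' locus id when no coordinates are available), then gene id, and numbered
#' `<prefix>1..N`. Unplaced scaffolds sort after numbered chromosomes.
#'
#' @param loci Tibble with `gene_id`, `chromosome` and optionally `start`.
#' @param prefix Name prefix (default `"Hsf"`).
#' @return The loci tibble in naming order with a `name` column appended.
#' @export
name_genes <- function(loci, prefix = "Hsf") {
  key <- if ("start" %in% names(loci)) loci$start else loci$gene_id
  num <- suppressWarnings(as.numeric(stringr::str_extract(loci$chromosome, "\\d+")))
  ord <- order(is.na(num), num, loci$chromosome, key, loci$gene_id)
  out <- loci[ord, , drop = FALSE]
  out$name <- paste0(prefix, seq_len(nrow(out)))
  out
}
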