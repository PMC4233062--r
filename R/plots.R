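# ggplot2 views of the main result types.

#' Plot domain architectures
#'
#' Horizontal protein backbones with the DBD, HR-A and HR-B regions drawn
#' as boxes; proteins are ordered as given.
#'
#' @param annotation Annotation tibble from [annotate_hsf()] (needs a
#'   protein length; pass the sequence tibble via `proteins` to derive it).
#' @param proteins Matching sequence tibble.
#' @return A ggplot object.
#' @export
plot_domain_architecture <- function(annotation, proteins) {
  ann <- annotation |>
    dplyr::mutate(length = nchar(proteins$seq[match(.data$id, proteins$id)]),
                  y = factor(.data$id, levels = rev(.data$id)))
  doms <- dplyr::bind_rows(
    dplyr::transmute(ann, id = .data$id, y = .data$y, domain = "DBD",
                     start = .data$dbd_start, end = .data$dbd_end),
    dplyr::transmute(ann, id = .data$id, y = .data$y, domain = "HR-A",
                     start = .data$hra_start, end = .data$hra_end),
    dplyr::transmute(ann, id = .data$id, y = .data$y, domain = "HR-B",
                     start = .data$hrb_start, end = .data$hrb_end)
  ) |>
    dplyr::filter(!is.na(.data$start))
  ggplot2::ggplot(ann) +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = .data$length,
                                       y = .data$y, yend = .data$y),
                          color = "grey60") +
    ggplot2::geom_rect(data = doms,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = as.numeric(.data$y) - 0.35,
                                    ymax = as.numeric(.data$y) + 0.35,
                                    fill = .data$domain)) +
    ggplot2::labs(x = "residue", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}

#' Plot heat-shock response trajectories
#'
#' Log2 fold-change over the treatment/recovery timepoints, one line per
#' gene, faceted by the assigned response pattern.
#'
#' @param response Tibble from [classify_heat_response()].
#' @return A ggplot object.
#' @export
plot_heat_response <- function(response) {
  long <- response |>
    tidyr::pivot_longer(dplyr::starts_with("fold_"),
                        names_to = "timepoint", values_to = "fold",
                        names_prefix = "fold_") |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = unique(.data$timepoint)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = log2(.data$fold),
                                     group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = "timepoint", y = "log2 fold-change vs control") +
    ggplot2::theme_minimal()
}

#' Plot the intron-count histogram
#'
#' @param histogram Tibble from [summarize_intron_counts()].
#' @return A ggplot object.
#' @export
plot_intron_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(x = factor(.data$n_introns),
                                          y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "introns per gene", y = "genes") +
    ggplot2::theme_minimal()
}
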