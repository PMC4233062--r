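# Comparative delta-CT quantification and heat-shock response patterns.

#' Relative expression from replicate Ct values
#'
#' Replicate Cts are averaged (arithmetic mean, the standard comparative-CT
#' convention); relative expression is `2^-(mean_target - mean_reference)`.
#' The delta-CT SD is propagated from the replicate SDs in quadrature.
#'
#' @param ct_target,ct_reference Numeric vectors of replicate Ct values.
#' @return One-row tibble `rel_expr`, `dct`, `dct_sd`.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  dct <- mean(ct_target) - mean(ct_reference)
  sd_t <- if (length(ct_target) > 1) sd(ct_target) else 0
  sd_r <- if (length(ct_reference) > 1) sd(ct_reference) else 0
  tibble(rel_expr = 2^(-dct), dct = dct, dct_sd = sqrt(sd_t^2 + sd_r^2))
}

#' Per-sample relative expression profiles from a Ct table
#'
#' @param ct Long Ct tibble (`gene`, `sample`, `replicate`, `ct`).
#' @param reference Reference gene id (default `"UBQ"`).
#' @return Tibble `gene`, `sample`, `rel_expr`, `dct`, `dct_sd`, `n_reps`.
#' @export
expression_profiles <- function(ct, reference = "UBQ") {
  if (!reference %in% ct$gene) {
    abort(paste0("reference gene '", reference, "' not present in the Ct table"))
  }
  ref <- ct[ct$gene == reference, ]
  targets <- ct[ct$gene != reference, ]
  purrr::map_dfr(
    split(targets, list(targets$gene, targets$sample), drop = TRUE),
    function(cell) {
      rcell <- ref[ref$sample == cell$sample[[1]], ]
      if (nrow(rcell) == 0) {
        return(tibble(gene = cell$gene[[1]], sample = cell$sample[[1]],
                      rel_expr = NA_real_, dct = NA_real_, dct_sd = NA_real_,
                      n_reps = nrow(cell)))
      }
      d <- delta_ct(cell$ct, rcell$ct)
      tibble(gene = cell$gene[[1]], sample = cell$sample[[1]],
             rel_expr = d$rel_expr, dct = d$dct, dct_sd = d$dct_sd,
             n_reps = nrow(cell))
    })
}

#' Fold-change of treated samples relative to a control sample
#'
#' The comparative delta-delta-CT fold: relative expression of the treated
#' sample divided by that of the control (so the control is 1-fold by
#' definition).
#'
#' @param profiles Profile tibble from [expression_profiles()].
#' @param control Control sample name (default `"CK"`).
#' @return Tibble `gene`, `sample`, `fold`.
#' @export
fold_change <- function(profiles, control = "CK") {
  ctrl <- profiles[profiles$sample == control, c("gene", "rel_expr")]
  names(ctrl)[2] <- "ctrl_expr"
  profiles |>
    dplyr::inner_join(ctrl, by = "gene") |>
    dplyr::mutate(fold = .data$rel_expr / .data$ctrl_expr) |>
    dplyr::select("gene", "sample", "fold")
}

#' Classify a heat-shock response trajectory
#'
#' Rules over the fold-changes at 1 h (heat shock) and 2 h/4 h (recovery),
#' relative to the untreated control:
#' * `immediate_up` — fold(1h) at or above `up_threshold`;
#' * `late_up` — not immediately induced, but rising monotonically through
#'   recovery to at least `up_threshold` at 4 h;
#' * `inhibited` — fold(1h) at or below `down_threshold` with no recovery
#'   rise to `up_threshold`;
#' * `unchanged` — everything else.
#'
#' @param fold_1h,fold_2h,fold_4h Fold-changes (vectors recycle).
#' @param up_threshold,down_threshold Call thresholds (defaults 2.0 / 0.5).
#' @return Character vector of pattern labels.
#' @export
classify_response <- function(fold_1h, fold_2h, fold_4h,
                              up_threshold = 2.0, down_threshold = 0.5) {
  n <- max(length(fold_1h), length(fold_2h), length(fold_4h))
  f1 <- rep_len(fold_1h, n)
  f2 <- rep_len(fold_2h, n)
  f4 <- rep_len(fold_4h, n)
  vapply(seq_len(n), function(i) {
    if (is.na(f1[[i]]) || is.na(f2[[i]]) || is.na(f4[[i]])) return(NA_character_)
    if (f1[[i]] >= up_threshold) return("immediate_up")
    if (f4[[i]] >= up_threshold && f2[[i]] > f1[[i]] && f4[[i]] > f2[[i]]) {
      return("late_up")
    }
    if (f1[[i]] <= down_threshold) return("inhibited")
    "unchanged"
  }, character(1))
}

#' Heat-shock response patterns for every gene in a Ct table
#'
#' Convenience wrapper: profiles, fold-changes vs the control and the
#' pattern call in one step.
#'
#' @param ct Long Ct tibble.
#' @param reference Reference gene (default `"UBQ"`).
#' @param control Control sample (default `"CK"`).
#' @param timepoints Treated/recovery samples in order (default
#'   `c("1h", "2h", "4h")`).
#' @param up_threshold,down_threshold Thresholds for [classify_response()].
#' @return Tibble `gene`, `fold_1h`, `fold_2h`, `fold_4h`, `pattern`.
#' @export
classify_heat_response <- function(ct, reference = "UBQ", control = "CK",
                                   timepoints = c("1h", "2h", "4h"),
                                   up_threshold = 2.0, down_threshold = 0.5) {
  folds <- fold_change(expression_profiles(ct, reference), control) |>
    dplyr::filter(.data$sample %in% timepoints) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fold",
                       names_prefix = "fold_")
  fc <- function(tp) folds[[paste0("fold_", tp)]]
  folds$pattern <- classify_response(fc(timepoints[[1]]), fc(timepoints[[2]]),
                                     fc(timepoints[[3]]),
                                     up_threshold, down_threshold)
  names(folds) <- sub("^fold_(\\d)", "fold_\\1", names(folds))
  folds
}

#' Compare expression between two genotypes
#'
#' Per gene and stage, the ratio of relative expression in the first
#' genotype (e.g. wild type) over the second (e.g. a fiberless mutant).
#' A gene is flagged differential when the ratio is at least `min_ratio`
#' (or at most `1/min_ratio`) at any stage.
#'
#' @param ct_a,ct_b Long Ct tibbles for the two genotypes.
#' @param reference Reference gene (default `"UBQ"`).
#' @param min_ratio Flagging threshold (default 2).
#' @return A list with `ratios` (tibble `gene`, `sample`, `ratio`) and
#'   `differential` (tibble `gene`, `max_ratio`, flagged genes only,
#'   `max_ratio` being the most extreme ratio across stages).
#' @export
compare_genotypes <- function(ct_a, ct_b, reference = "UBQ", min_ratio = 2) {
  pa <- expression_profiles(ct_a, reference)
  pb <- expression_profiles(ct_b, reference)
  ratios <- dplyr::inner_join(pa[, c("gene", "sample", "rel_expr")],
                              pb[, c("gene", "sample", "rel_expr")],
                              by = c("gene", "sample"),
                              suffix = c("_a", "_b")) |>
    dplyr::mutate(ratio = .data$rel_expr_a / .data$rel_expr_b) |>
    dplyr::select("gene", "sample", "ratio")
  differential <- ratios |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      max_ratio = .data$ratio[which.max(abs(log2(.data$ratio)))],
      mean_ratio = 2^mean(log2(.data$ratio)), # geometric mean across stages
      .groups = "drop") |>
    dplyr::filter(.data$max_ratio >= min_ratio | .data$max_ratio <= 1 / min_ratio)
  list(ratios = ratios, differential = differential)
}
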