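#' Plot region-level balanced accuracies
#'
#' Dot plot of mean balanced accuracy per ROI (one panel per contrast),
#' FDR-significant regions highlighted.
#'
#' @param classification Tibble from [classify_regions()] or the
#'   `classification` element of a pipeline run.
#' @return A ggplot object.
#' @export
plot_bca <- function(classification) {
  ggplot2::ggplot(
    classification,
    ggplot2::aes(x = stats::reorder(.data$roi, .data$bca_mean),
                 y = .data$bca_mean, colour = .data$significant)
  ) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "FDR significant") +
    ggplot2::labs(x = NULL, y = "balanced accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution with the observed accuracy
#'
#' @param object A `region_perm_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(bca = object$null_bcas),
                  ggplot2::aes(x = .data$bca)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$bca_mean, colour = "firebrick") +
    ggplot2::labs(x = "null balanced accuracy (%)", y = "count",
                  subtitle = sprintf("observed %.1f%%, p = %.3g",
                                     object$bca_mean, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' Plot top feature scores
#'
#' Horizontal bar chart of the signed rank-sum feature scores with the largest
#' magnitudes.
#'
#' @param object A `feature_scores` tibble.
#' @param n Number of features displayed (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_scores <- function(object, n = 20, ...) {
  d <- object |>
    dplyr::arrange(dplyr::desc(abs(.data$score))) |>
    dplyr::slice_head(n = n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature_id, abs(.data$score)),
    y = .data$score, fill = .data$p_fdr < 0.01
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                               name = "p_FDR < 0.01") +
    ggplot2::labs(x = NULL, y = "signed rank-sum score (z)") +
    ggplot2::theme_minimal()
}

#' Plot per-minute functional connectivity
#'
#' Group-mean per-minute FC traces (with per-animal points) for one
#' seed-target pair across periods.
#'
#' @param fc_minutes Tibble from [fc_per_minute()].
#' @param target Target ROI to display.
#' @return A ggplot object.
#' @export
plot_fc_minutes <- function(fc_minutes, target) {
  d <- dplyr::filter(fc_minutes, .data$target == !!target)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minute, y = .data$r,
                                  colour = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$period)) +
    ggplot2::labs(x = "minute", y = "FC (Pearson r)",
                  title = paste(unique(d$seed), "-", target)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
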