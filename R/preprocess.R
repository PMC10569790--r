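#' Well-behaved feature mask
#'
#' Identifies features that are finite for every animal, period and ROI in the
#' supplied feature table and non-constant across animals within every
#' (ROI, period) cell. Mirrors the removal of "poorly behaved" features
#' (NaN / Inf / degenerate outputs) before any statistics are computed; the
#' mask is shared across all ROIs being compared.
#'
#' @param features Long feature tibble, as from [feature_matrix()] or
#'   [delta_features()] (a `value` or `delta` column is used).
#' @return Character vector of retained `feature_id`s, in catalogue order.
#' @export
well_behaved_mask <- function(features) {
  val_col <- if ("delta" %in% names(features)) "delta" else "value"
  grouping <- intersect(c("roi", "period"), names(features))
  ok <- features |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      all_finite = all(is.finite(.data[[val_col]])),
      .groups = "drop"
    )
  nonconst <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("feature_id", grouping)))) |>
    dplyr::summarise(v = var(.data[[val_col]]), .groups = "drop") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      non_constant = all(is.finite(.data$v) & .data$v > 0),
      .groups = "drop"
    )
  keep <- dplyr::inner_join(ok, nonconst, by = "feature_id") |>
    dplyr::filter(.data$all_finite, .data$non_constant) |>
    dplyr::pull("feature_id")
  keep <- intersect(unique(features$feature_id), keep)
  if (length(keep) == 0) {
    stop("no well-behaved features retained", call. = FALSE)
  }
  keep
}

#' Baseline-subtracted feature changes
#'
#' Computes `post - baseline` per animal, ROI and feature. Both periods must
#' be present for every (animal, roi, feature) key.
#'
#' @param features Long feature tibble from [feature_matrix()] with a `period`
#'   column containing `"baseline"` and `"post"`.
#' @return Tibble with columns `animal`, `group`, `roi`, `feature_id`,
#'   `delta`.
#' @export
delta_features <- function(features) {
  if (!all(c("baseline", "post") %in% unique(features$period))) {
    stop("feature table must contain both 'baseline' and 'post' periods",
         call. = FALSE)
  }
  complete <- features |>
    dplyr::distinct(.data$animal, .data$roi, .data$feature_id, .data$period) |>
    dplyr::count(.data$animal, .data$roi, .data$feature_id)
  if (any(complete$n != 2)) {
    stop("misaligned feature matrices: every (animal, roi, feature) needs both periods",
         call. = FALSE)
  }
  wide <- features |>
    dplyr::select(dplyr::all_of(c("animal", "group", "roi", "feature_id",
                                  "period", "value"))) |>
    tidyr::pivot_wider(names_from = "period", values_from = "value")
  wide |>
    dplyr::mutate(delta = .data$post - .data$baseline) |>
    dplyr::select(dplyr::all_of(c("animal", "group", "roi", "feature_id", "delta")))
}

#' Outlier-robust sigmoidal normalization
#'
#' Scaled robust sigmoid: `1 / (1 + exp(-(x - median) / (1.35 * IQR)))`,
#' mapping a feature column into (0, 1) while damping the influence of
#' outliers. The 1.35 constant converts the IQR to a Gaussian-equivalent
#' standard deviation.
#'
#' @param x Numeric vector (one feature column).
#' @return Values in (0, 1); all-`NA` with a warning when `IQR(x) == 0`.
#' @examples
#' robust_sigmoid(c(1, 2, 3, 10))
#' @export
robust_sigmoid <- function(x) {
  iqr <- IQR(x)
  if (!is.finite(iqr) || iqr == 0) {
    warning("zero IQR; column cannot be sigmoid-normalized", call. = FALSE)
    return(rep(NA_real_, length(x)))
  }
  1 / (1 + exp(-(x - median(x)) / (1.35 * iqr)))
}

#' Normalize a delta-feature table per feature column
#'
#' Applies [robust_sigmoid()] independently to each feature within each ROI,
#' across all animals jointly (the two groups entering a classification are
#' normalized together). Zero-IQR columns are dropped with a warning.
#'
#' @param delta Tibble from [delta_features()].
#' @return Tibble of the same shape with `delta` replaced by its normalized
#'   value; zero-IQR (roi, feature) cells removed.
#' @export
normalize_features <- function(delta) {
  out <- delta |>
    dplyr::group_by(.data$roi, .data$feature_id) |>
    dplyr::mutate(delta = suppressWarnings(robust_sigmoid(.data$delta))) |>
    dplyr::ungroup()
  dropped <- out |>
    dplyr::filter(is.na(.data$delta)) |>
    dplyr::distinct(.data$roi, .data$feature_id)
  if (nrow(dropped) > 0) {
    warning(sprintf("%d zero-IQR feature column(s) dropped during normalization",
                    nrow(dropped)), call. = FALSE)
    out <- dplyr::anti_join(out, dropped, by = c("roi", "feature_id"))
  }
  out
}

# wide animals x features matrix for one ROI (internal)
delta_matrix <- function(delta, roi, groups = NULL, feature_ids = NULL) {
  d <- dplyr::filter(delta, .data$roi == !!roi)
  if (!is.null(groups)) d <- dplyr::filter(d, .data$group %in% groups)
  if (!is.null(feature_ids)) d <- dplyr::filter(d, .data$feature_id %in% feature_ids)
  if (nrow(d) == 0) stop("no rows for roi '", roi, "'", call. = FALSE)
  wide <- tidyr::pivot_wider(d, id_cols = dplyr::all_of(c("animal", "group")),
                             names_from = "feature_id", values_from = "delta")
  X <- as.matrix(wide[, setdiff(names(wide), c("animal", "group"))])
  rownames(X) <- wide$animal
  list(X = X, group = factor(wide$group, levels = unique(wide$group)),
       animal = wide$animal)
}
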