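# Pearson r per non-overlapping window; constant windows -> NA
windowed_cor <- function(a, b, window = 60) {
  n <- min(length(a), length(b))
  m <- floor(n / window)
  vapply(seq_len(m), function(w) {
    i <- ((w - 1) * window + 1):(w * window)
    if (sd(a[i]) == 0 || sd(b[i]) == 0) return(NA_real_)
    cor(a[i], b[i])
  }, numeric(1))
}

#' Per-minute functional connectivity between a seed and target ROIs
#'
#' Pearson correlation per non-overlapping 60-sample window (one minute at a
#' 1 s sampling interval) between the seed ROI and every target ROI, per
#' animal and period. Constant windows yield `NA` and are excluded from the
#' period means downstream.
#'
#' @param cohort_ts Long cohort tibble (`animal`, `group`, `roi`, `period`,
#'   `t`, `value`).
#' @param seed_roi Seed ROI label.
#' @param targets Target ROI labels (default: all other ROIs).
#' @param window Window length in samples (default 60).
#' @return Tibble `animal`, `group`, `seed`, `target`, `period`, `minute`,
#'   `r`.
#' @export
fc_per_minute <- function(cohort_ts, seed_roi, targets = NULL, window = 60) {
  rois <- unique(cohort_ts$roi)
  if (!seed_roi %in% rois) stop("seed ROI not present in data", call. = FALSE)
  if (is.null(targets)) targets <- setdiff(rois, seed_roi)
  ts_sorted <- dplyr::arrange(cohort_ts, .data$animal, .data$roi,
                              .data$period, .data$t)
  seed_tbl <- dplyr::filter(ts_sorted, .data$roi == seed_roi)
  seed_series <- split(seed_tbl$value,
                       paste(seed_tbl$animal, seed_tbl$period, sep = "\r"))
  targ_tbl <- dplyr::filter(ts_sorted, .data$roi %in% targets)
  targ_tbl |>
    dplyr::group_by(.data$animal, .data$group, .data$roi, .data$period) |>
    dplyr::group_modify(function(d, key) {
      s <- seed_series[[paste(key$animal, key$period, sep = "\r")]]
      r <- windowed_cor(s, d$value, window)
      tibble::tibble(minute = seq_along(r), r = r)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(seed = seed_roi) |>
    dplyr::rename(target = "roi") |>
    dplyr::select(dplyr::all_of(c("animal", "group", "seed", "target",
                                  "period", "minute", "r")))
}

#' Summarise per-minute FC into period means and deltas
#'
#' @param fc_minutes Tibble from [fc_per_minute()].
#' @return Tibble `animal`, `group`, `seed`, `target`, `baseline_mean`,
#'   `post_mean`, `delta_fc` (post minus baseline).
#' @export
fc_summary <- function(fc_minutes) {
  fc_minutes |>
    dplyr::group_by(.data$animal, .data$group, .data$seed, .data$target,
                    .data$period) |>
    dplyr::summarise(fc = mean(.data$r, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "period", values_from = "fc") |>
    dplyr::rename(baseline_mean = "baseline", post_mean = "post") |>
    dplyr::mutate(delta_fc = .data$post_mean - .data$baseline_mean)
}

#' Test baseline FC against zero per ROI pair
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the per-animal baseline
#' FC means against zero, for every seed-target pair, pooling all groups, with
#' BH-FDR correction across pairs.
#'
#' @param fcs Tibble from [fc_summary()].
#' @param fdr_level Significance threshold on FDR-corrected p (default 0.01).
#' @return Tibble `seed`, `target`, `median_fc`, `p`, `p_fdr`, `significant`.
#' @export
baseline_fc_test <- function(fcs, fdr_level = 0.01) {
  out <- fcs |>
    dplyr::group_by(.data$seed, .data$target) |>
    dplyr::summarise(
      n = sum(is.finite(.data$baseline_mean)),
      median_fc = median(.data$baseline_mean, na.rm = TRUE),
      p = {
        v <- .data$baseline_mean[is.finite(.data$baseline_mean)]
        if (length(v) < 6) stop("need at least 6 animals per pair", call. = FALSE)
        wilcoxon_signed_rank(v)
      },
      .groups = "drop"
    )
  out$p_fdr <- bh_fdr(out$p)
  out$significant <- out$p_fdr < fdr_level
  out
}

#' Permutation test for group differences in FC change
#'
#' For each group contrast and ROI pair, the statistic is the difference in
#' mean delta-FC (second group minus first); the null shuffles group labels
#' among the animals of the two groups. Two-sided add-one p-values are
#' FDR-corrected jointly over all (pair x contrast) tests.
#'
#' @param fcs Tibble from [fc_summary()] (must contain a `group` column).
#' @param contrasts List of 2-element character vectors
#'   `c(reference, stimulation)`.
#' @param n_perm Number of permutations (default 5000).
#' @param fdr_level Significance threshold on corrected p (default 0.05).
#' @param seed Integer seed.
#' @return Tibble `contrast`, `seed`, `target`, `delta_diff`, `p_perm`,
#'   `p_fdr`, `significant`.
#' @export
group_delta_fc_test <- function(fcs, contrasts, n_perm = 5000,
                                fdr_level = 0.05, seed = 1) {
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  res <- purrr::imap_dfr(contrasts, function(ct, i) {
    d <- dplyr::filter(fcs, .data$group %in% ct, is.finite(.data$delta_fc))
    if (!all(ct %in% d$group)) stop("empty group in contrast", call. = FALSE)
    wide <- tidyr::pivot_wider(d, id_cols = dplyr::all_of(c("animal", "group")),
                               names_from = c("seed", "target"),
                               names_sep = "->", values_from = "delta_fc")
    X <- as.matrix(wide[, setdiff(names(wide), c("animal", "group"))])
    is2 <- wide$group == ct[2]
    diff_of <- function(sel) colMeans(X[sel, , drop = FALSE]) -
      colMeans(X[!sel, , drop = FALSE])
    obs <- diff_of(is2)
    nulls <- withr::with_seed(seed + i, {
      vapply(seq_len(n_perm), function(b) diff_of(sample(is2)),
             numeric(length(obs)))
    })
    nulls <- matrix(nulls, nrow = length(obs))
    p <- vapply(seq_along(obs), function(j) {
      perm_pvalue(abs(obs[j]), abs(nulls[j, ]))
    }, numeric(1))
    pair <- strsplit(colnames(X), "->", fixed = TRUE)
    tibble::tibble(
      contrast = paste(ct, collapse = "-vs-"),
      seed = vapply(pair, `[`, character(1), 1),
      target = vapply(pair, `[`, character(1), 2),
      delta_diff = unname(obs),
      p_perm = p
    )
  })
  res$p_fdr <- bh_fdr(res$p_perm)
  res$significant <- res$p_fdr < fdr_level
  res
}

#' Correlation between behavior and FC change for one ROI pair
#'
#' Pearson correlation (two-sided t-based p) between per-animal rotation
#' asymmetry (contraversive minus ipsiversive rotations) and delta-FC of one
#' seed-target pair.
#'
#' @param behavior Tibble with columns `animal`, `rotation_asymmetry`.
#' @param fcs Tibble from [fc_summary()].
#' @param target Target ROI of the pair (the seed is taken from `fcs`).
#' @return Tibble with `target`, `r`, `p`, `n`.
#' @export
behavior_fc_correlation <- function(behavior, fcs, target) {
  d <- fcs |>
    dplyr::filter(.data$target == !!target) |>
    dplyr::inner_join(behavior, by = "animal") |>
    dplyr::filter(is.finite(.data$delta_fc), is.finite(.data$rotation_asymmetry))
  if (nrow(d) < 5) stop("need at least 5 shared animals", call. = FALSE)
  ct <- cor.test(d$delta_fc, d$rotation_asymmetry)
  tibble::tibble(target = target, r = unname(ct$estimate), p = ct$p.value,
                 n = nrow(d))
}
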