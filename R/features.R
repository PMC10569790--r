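#' Curated time-series feature catalogue
#'
#' A fixed, ordered catalogue of interpretable time-series statistics covering
#' the feature families that discriminate chemogenetically modulated BOLD
#' dynamics: distribution moments, linear autocorrelation and correlation
#' timescales, automutual information, Fourier-spectrum properties,
#' autoregressive model fits, fluctuation analysis, entropy, stationarity and
#' outlier statistics. All families except `distribution` are computed on the
#' z-scored series, so they are invariant to affine transforms of the input.
#'
#' @return A tibble with columns `feature_id`, `family`, `params` (a compact
#'   `key=value` string recording estimator settings), in deterministic order.
#' @examples
#' feature_catalog()
#' @export
feature_catalog <- function() {
  tibble::tribble(
    ~feature_id,        ~family,                   ~params,
    "mean",             "distribution",            "raw",
    "sd",               "distribution",            "raw",
    "skewness",         "distribution",            "raw;type=3",
    "kurtosis",         "distribution",            "raw;type=3;excess",
    "median",           "distribution",            "raw",
    "iqr",              "distribution",            "raw;type=7",
    "ac_1",             "autocorrelation",         "lag=1;biased",
    "ac_2",             "autocorrelation",         "lag=2;biased",
    "ac_3",             "autocorrelation",         "lag=3;biased",
    "ac_4",             "autocorrelation",         "lag=4;biased",
    "ac_5",             "autocorrelation",         "lag=5;biased",
    "ac_6",             "autocorrelation",         "lag=6;biased",
    "ac_7",             "autocorrelation",         "lag=7;biased",
    "ac_8",             "autocorrelation",         "lag=8;biased",
    "ac_9",             "autocorrelation",         "lag=9;biased",
    "ac_10",            "autocorrelation",         "lag=10;biased",
    "ac_first_zero",    "autocorrelation",         "first lag with acf<0;max=n/4",
    "ac_first_1e",      "autocorrelation",         "first lag with acf<1/e;max=n/4",
    "ac_decay_time",    "autocorrelation",         "interpolated 1/e crossing of acf;max=n/4",
    "ami_1",            "automutual-information",  "lag=1;bins=10;equiprobable",
    "ami_2",            "automutual-information",  "lag=2;bins=10;equiprobable",
    "low_power_frac",   "spectral",                "band=0.01-0.1;total=0.01-0.25;fs=1",
    "spectral_centroid","spectral",                "total=0.01-0.25;fs=1",
    "spectral_entropy", "spectral",                "total=0.01-0.25;fs=1;nats",
    "ar2_phi1",         "ar-model",                "yule-walker;order=2",
    "ar2_phi2",         "ar-model",                "yule-walker;order=2",
    "ar2_sigma2",       "ar-model",                "yule-walker;order=2;resid var",
    "ar_aic_order",     "ar-model",                "yule-walker;aic;max order=8",
    "dfa_alpha",        "fluctuation",             "windows=10-100;log-spaced;linear detrend",
    "sampen_m2",        "entropy",                 "m=2;r=0.2*sd",
    "permen_3",         "entropy",                 "order=3;nats",
    "statav_5",         "stationarity",            "segments=5",
    "max_abs_z",        "outlier",                 "on z-scored series",
    "prop_z_gt2",       "outlier",                 "fraction |z|>2"
  )
}

#' Autocorrelation at a fixed lag
#'
#' Mean-removed, biased (divisor-n) normalized autocorrelation.
#'
#' @param ts Numeric series.
#' @param lag Positive integer lag, less than the series length.
#' @return Correlation in \[-1, 1\]; `NaN` for a constant series.
#' @export
acf_lag <- function(ts, lag) {
  stopifnot(length(lag) == 1, lag >= 0, lag < length(ts))
  if (sd(ts) == 0) return(NaN)
  drop(acf(ts, lag.max = max(lag, 1), plot = FALSE, demean = TRUE)$acf)[lag + 1]
}

#' Correlation timescale estimates
#'
#' Smallest lags at which the autocorrelation function first drops below zero
#' and below 1/e, scanned up to `length(ts) / 4`. If the threshold is never
#' crossed, the scan limit is returned.
#'
#' @param ts Numeric series (non-constant).
#' @return Named list `first_zero_lag`, `first_1e_lag` (integers); `NaN`
#'   entries for a constant series.
#' @export
ac_timescales <- function(ts) {
  max_lag <- floor(length(ts) / 4)
  if (sd(ts) == 0) return(list(first_zero_lag = NaN, first_1e_lag = NaN))
  a <- drop(acf(ts, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)[-1]
  fz <- which(a < 0)
  f1e <- which(a < exp(-1))
  list(
    first_zero_lag = if (length(fz)) fz[1] else max_lag,
    first_1e_lag = if (length(f1e)) f1e[1] else max_lag
  )
}

#' Continuous correlation decay time
#'
#' Correlation timescale estimated as the (linearly interpolated) lag at which
#' the autocorrelation function first crosses 1/e. Unlike the integer lag
#' indices of [ac_timescales()], this estimate varies continuously with the
#' decay rate, which makes it far better behaved in rank-based group
#' comparisons of small cohorts.
#'
#' @param ts Numeric series (non-constant).
#' @return Positive decay time in samples (scan limit `length(ts)/4` if the
#'   ACF never crosses 1/e); `NaN` for a constant series.
#' @export
ac_decay_time <- function(ts) {
  max_lag <- floor(length(ts) / 4)
  if (sd(ts) == 0) return(NaN)
  a <- drop(acf(ts, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  thr <- exp(-1)
  below <- which(a < thr) # includes lag 0 at index 1 (a[1] = 1 > thr always)
  if (length(below) == 0) return(as.numeric(max_lag))
  k <- below[1] # 1-based index; lag = k - 1
  (k - 2) + (a[k - 1] - thr) / (a[k - 1] - a[k])
}

# raw periodogram (no taper, no padding), frequencies in Hz
periodogram <- function(ts, fs = 1) {
  p <- spec.pgram(ts, taper = 0, detrend = FALSE, demean = TRUE,
                  fast = FALSE, plot = FALSE)
  list(freq = p$freq * fs, spec = p$spec)
}

#' Low-frequency power fraction
#'
#' Periodogram power inside a low-frequency band divided by power inside the
#' full analysis band; an fALFF-like quantity for band-limited BOLD signals.
#'
#' @param ts Numeric series (length >= 64).
#' @param fs Sampling rate in Hz.
#' @param band Low-frequency band `(f_lo, f_hi)` in Hz.
#' @param total_band Full analysis band in Hz.
#' @return Fraction in \[0, 1\]; `NaN` if the total band carries no power.
#' @export
low_freq_power_fraction <- function(ts, fs = 1, band = c(0.01, 0.1),
                                    total_band = c(0.01, 0.25)) {
  stopifnot(length(ts) >= 64)
  pg <- periodogram(ts, fs)
  in_total <- pg$freq >= total_band[1] & pg$freq <= total_band[2]
  in_band <- pg$freq >= band[1] & pg$freq <= band[2]
  tot <- sum(pg$spec[in_total])
  if (!is.finite(tot) || tot <= 0) return(NaN)
  sum(pg$spec[in_band & in_total]) / tot
}

# spectral centroid and entropy over the analysis band
spectral_summaries <- function(ts, fs = 1, total_band = c(0.01, 0.25)) {
  pg <- periodogram(ts, fs)
  keep <- pg$freq >= total_band[1] & pg$freq <= total_band[2]
  s <- pg$spec[keep]; f <- pg$freq[keep]
  tot <- sum(s)
  if (!is.finite(tot) || tot <= 0) return(list(centroid = NaN, entropy = NaN))
  p <- s / tot
  list(centroid = sum(f * p), entropy = -sum(p[p > 0] * log(p[p > 0])))
}

#' Automutual information with equiprobable bins
#'
#' Histogram estimate (in nats) of the mutual information between `ts(t)` and
#' `ts(t + lag)`, with each marginal discretized into `n_bins` equiprobable
#' bins (quantile bins), which makes the estimate invariant under strictly
#' monotone transforms of the series.
#'
#' @param ts Numeric series.
#' @param lag Positive integer lag.
#' @param n_bins Number of quantile bins (default 10).
#' @return Non-negative mutual information in nats; `NaN` when the quantile
#'   binning degenerates (fewer than 2 distinct bins).
#' @export
automutual_info <- function(ts, lag, n_bins = 10) {
  n <- length(ts)
  stopifnot(lag >= 1, lag < n)
  x1 <- ts[seq_len(n - lag)]
  x2 <- ts[seq_len(n - lag) + lag]
  bin <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(NULL)
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  b1 <- bin(x1); b2 <- bin(x2)
  if (is.null(b1) || is.null(b2)) return(NaN)
  joint <- table(b1, b2) / length(b1)
  p1 <- rowSums(joint); p2 <- colSums(joint)
  pij <- as.numeric(joint)
  pind <- as.numeric(outer(p1, p2))
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / pind[nz]))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Slope of `log F(s)` against `log s` for the linearly detrended fluctuation
#' function of the cumulative profile, over log-spaced window sizes.
#'
#' @param ts Numeric series; length must be at least 4x the largest window.
#' @param window_range Smallest and largest window sizes (default 10 to 100).
#' @param n_scales Number of log-spaced window sizes (default 10).
#' @return Positive scaling exponent alpha; `NaN` for degenerate input.
#' @export
dfa_alpha <- function(ts, window_range = c(10, 100), n_scales = 10) {
  n <- length(ts)
  if (n < 4 * window_range[2]) {
    stop("series too short for the requested DFA window range", call. = FALSE)
  }
  if (sd(ts) == 0) return(NaN)
  y <- cumsum(ts - mean(ts))
  sizes <- unique(round(exp(seq(log(window_range[1]), log(window_range[2]),
                                length.out = n_scales))))
  fl <- vapply(sizes, function(s) {
    m <- floor(n / s)
    seg <- matrix(y[seq_len(m * s)], nrow = s)
    tt <- cbind(1, seq_len(s))
    # residual maker for per-segment linear detrending
    res <- seg - tt %*% solve(crossprod(tt), crossprod(tt, seg))
    sqrt(mean(res^2))
  }, numeric(1))
  unname(coef(lm(log(fl) ~ log(sizes)))[2])
}

#' Sample entropy
#'
#' `SampEn(m, r)`: negative log of the conditional probability that sequences
#' matching for `m` points (Chebyshev distance <= `r`, self-matches excluded)
#' also match for `m + 1` points.
#'
#' @param ts Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(ts)`.
#' @return Non-negative entropy in nats; `NaN` when no template matches exist.
#' @export
sample_entropy <- function(ts, m = 2, r = 0.2 * sd(ts)) {
  if (!is.finite(r) || r <= 0) return(NaN)
  .sampen_cpp(as.numeric(ts), as.integer(m), r)
}

#' Permutation entropy
#'
#' Shannon entropy (nats) of the distribution of ordinal patterns of
#' `order` consecutive values.
#'
#' @param ts Numeric series.
#' @param order Pattern length (default 3).
#' @return Entropy in nats, between 0 and `log(factorial(order))`.
#' @export
permutation_entropy <- function(ts, order = 3) {
  n <- length(ts)
  stopifnot(n > order)
  if (sd(ts) == 0) return(NaN)
  idx <- seq_len(n - order + 1)
  emb <- vapply(seq_len(order), function(k) ts[idx + k - 1], numeric(length(idx)))
  # within-window ranks (ties broken by position), encoded base-`order`
  code <- integer(length(idx))
  for (i in seq_len(order)) {
    ri <- rep(0L, length(idx))
    for (j in seq_len(order)) {
      if (j == i) next
      # element i outranks j when larger, or equal with a later position
      ri <- ri + if (j < i) (emb[, i] >= emb[, j]) else (emb[, i] > emb[, j])
    }
    code <- code * order + ri
  }
  p <- tabulate(code + 1L, nbins = order^order)
  p <- p[p > 0] / length(code)
  -sum(p * log(p))
}

#' StatAv stationarity index
#'
#' Standard deviation of the means of `n_seg` non-overlapping segments,
#' divided by the overall standard deviation. Values near
#' `1 / sqrt(length(ts) / n_seg)` indicate a stationary mean.
#'
#' @param ts Numeric series.
#' @param n_seg Number of segments (default 5).
#' @return Non-negative index; `NaN` for a constant series.
#' @export
stat_av <- function(ts, n_seg = 5) {
  n <- length(ts)
  stopifnot(n >= 2 * n_seg)
  if (sd(ts) == 0) return(NaN)
  s <- floor(n / n_seg)
  seg_means <- colMeans(matrix(ts[seq_len(s * n_seg)], nrow = s))
  sd(seg_means) / sd(ts)
}

#' Extract the full feature vector for one series
#'
#' Computes every catalogue feature on a single time series. Features in the
#' `distribution` family are computed on the raw series; all other families on
#' the z-scored series. Non-finite outputs (degenerate inputs, undefined
#' estimates) are flagged, never raised as errors, so that poorly behaved
#' features can be filtered in a separate, testable step.
#'
#' @param ts Numeric series, length >= 128.
#' @param catalog Feature catalogue tibble, as from [feature_catalog()].
#' @param fs Sampling rate in Hz (default 1).
#' @return Tibble with columns `feature_id`, `family`, `value`, `finite`,
#'   aligned to the catalogue order.
#' @examples
#' extract_features(rnorm(256))
#' @export
extract_features <- function(ts, catalog = feature_catalog(), fs = 1) {
  ts <- as.numeric(ts)
  if (length(ts) < 128) stop("series must have at least 128 samples", call. = FALSE)
  s <- sd(ts)
  z <- if (is.finite(s) && s > 0) (ts - mean(ts)) / s else rep(NaN, length(ts))

  safe <- function(expr) {
    v <- tryCatch(suppressWarnings(expr), error = function(e) NaN)
    if (length(v) != 1 || !is.numeric(v)) NaN else as.numeric(v)
  }

  acs <- if (all(is.finite(z))) {
    drop(acf(z, lag.max = 10, plot = FALSE, demean = TRUE)$acf)[-1]
  } else rep(NaN, 10)
  tsc <- if (all(is.finite(z))) ac_timescales(z) else
    list(first_zero_lag = NaN, first_1e_lag = NaN)
  sp <- if (all(is.finite(z))) spectral_summaries(z, fs = fs) else
    list(centroid = NaN, entropy = NaN)
  ar2 <- tryCatch(
    if (all(is.finite(z))) ar.yw(z, aic = FALSE, order.max = 2, demean = TRUE)
    else NULL, error = function(e) NULL)
  ar_aic <- safe(if (all(is.finite(z)))
    ar.yw(z, aic = TRUE, order.max = 8, demean = TRUE)$order else NaN)

  vals <- c(
    mean = mean(ts),
    sd = s,
    skewness = safe(e1071::skewness(ts)),
    kurtosis = safe(e1071::kurtosis(ts)),
    median = median(ts),
    iqr = IQR(ts),
    setNames(acs, paste0("ac_", 1:10)),
    ac_first_zero = as.numeric(tsc$first_zero_lag),
    ac_first_1e = as.numeric(tsc$first_1e_lag),
    ac_decay_time = safe(ac_decay_time(z)),
    ami_1 = safe(automutual_info(z, 1, n_bins = 10)),
    ami_2 = safe(automutual_info(z, 2, n_bins = 10)),
    low_power_frac = safe(low_freq_power_fraction(z, fs = fs)),
    spectral_centroid = sp$centroid,
    spectral_entropy = sp$entropy,
    ar2_phi1 = if (is.null(ar2)) NaN else ar2$ar[1],
    ar2_phi2 = if (is.null(ar2)) NaN else ar2$ar[2],
    ar2_sigma2 = if (is.null(ar2)) NaN else ar2$var.pred,
    ar_aic_order = ar_aic,
    dfa_alpha = safe(dfa_alpha(z)),
    sampen_m2 = safe(sample_entropy(z, m = 2, r = 0.2)),
    permen_3 = safe(permutation_entropy(z, order = 3)),
    statav_5 = safe(stat_av(z, n_seg = 5)),
    max_abs_z = if (all(is.finite(z))) max(abs(z)) else NaN,
    prop_z_gt2 = if (all(is.finite(z))) mean(abs(z) > 2) else NaN
  )
  out <- tibble::tibble(
    feature_id = catalog$feature_id,
    family = catalog$family,
    value = unname(vals[catalog$feature_id])
  )
  out$finite <- is.finite(out$value)
  out
}

#' Compute the feature matrix for a cohort of ROI time series
#'
#' Applies [extract_features()] to every (animal, ROI, period) series of a
#' long-format cohort table.
#'
#' @param cohort_ts Tibble with columns `animal`, `group`, `roi`, `period`,
#'   `t`, `value` (one row per sample).
#' @param catalog Feature catalogue.
#' @param fs Sampling rate in Hz.
#' @return Long tibble with columns `animal`, `group`, `roi`, `period`,
#'   `feature_id`, `family`, `value`, `finite`.
#' @export
feature_matrix <- function(cohort_ts, catalog = feature_catalog(), fs = 1) {
  required <- c("animal", "group", "roi", "period", "t", "value")
  missing_cols <- setdiff(required, names(cohort_ts))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort_ts |>
    dplyr::arrange(.data$animal, .data$roi, .data$period, .data$t) |>
    dplyr::group_by(.data$animal, .data$group, .data$roi, .data$period) |>
    dplyr::group_modify(function(d, key) extract_features(d$value, catalog, fs = fs)) |>
    dplyr::ungroup()
}
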