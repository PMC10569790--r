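test_that("acf_lag uses the biased mean-removed estimator", {
  alt <- rep(c(1, -1), 50)
  expect_equal(acf_lag(alt, 1), -99 / 100) # closed form for alternating series
  expect_equal(acf_lag(rnorm(100), 0), 1)
  x <- make_ar1(1e5, 0.6, seed = 2)
  expect_equal(acf_lag(x, 1), 0.6, tolerance = 0.01 / 0.6)
  expect_true(is.nan(acf_lag(rep(2, 50), 1)))
})

test_that("correlation timescales match closed-form AR(1) behavior", {
  alt <- rep(c(1, -1), 60)
  expect_equal(ac_timescales(alt)$first_zero_lag, 1)
  # phi^5 = 0.328 < 1/e <= phi^4 = 0.41
  x <- make_ar1(2e5, 0.8, seed = 3)
  expect_equal(ac_timescales(x)$first_1e_lag, 5)
  expect_equal(ac_decay_time(x), -1 / log(0.8), tolerance = 0.05)
  # white noise crosses zero almost immediately
  crossings <- vapply(1:10, function(s) {
    ac_timescales(withr::with_seed(s, rnorm(500)))$first_zero_lag
  }, numeric(1))
  expect_gte(mean(crossings <= 3), 0.8)
})

test_that("low-frequency power fraction localizes spectral mass", {
  t <- seq_len(900)
  expect_gt(low_freq_power_fraction(sin(2 * pi * 0.05 * t)), 0.99)
  expect_lt(low_freq_power_fraction(sin(2 * pi * 0.2 * t)), 0.01)
  # flat spectrum: fraction ~ band width / total width = 0.09 / 0.24
  x <- withr::with_seed(4, rnorm(2^14))
  expect_equal(low_freq_power_fraction(x), 0.375, tolerance = 0.05 / 0.375)
})

test_that("automutual information behaves at independence and near-identity", {
  # near-identity coupling: staircase series, lag-1 pairs almost all equal
  w <- rep(withr::with_seed(9, rnorm(45)), each = 20)
  expect_gt(automutual_info(w, 1), 0.75 * log(10))
  # equiprobable bins make the estimate rank-invariant (exact)
  x <- make_ar1(900, 0.5, seed = 5)
  expect_equal(automutual_info(x, 1), automutual_info(exp(x), 1))
  # independence: below a shuffle-derived bias threshold
  z <- withr::with_seed(6, rnorm(5000))
  bias <- vapply(1:20, function(s) {
    automutual_info(withr::with_seed(100 + s, sample(z)), 1)
  }, numeric(1))
  expect_lt(automutual_info(z, 1), mean(bias) + 4 * sd(bias))
  expect_true(is.nan(automutual_info(rep(c(0, 1), 450), 1)))
})

test_that("DFA exponent recovers theoretical scaling", {
  w <- withr::with_seed(7, rnorm(1e4))
  expect_equal(dfa_alpha(w), 0.5, tolerance = 0.1 / 0.5)
  expect_equal(dfa_alpha(cumsum(w)), 1.5, tolerance = 0.1 / 1.5)
  x <- make_ar1(1000, 0.4, seed = 8)
  expect_equal(dfa_alpha(x), dfa_alpha(7.3 * x)) # scale invariance
  expect_error(dfa_alpha(rnorm(100)), "too short")
})

test_that("sample entropy agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  for (s in 1:4) {
    x <- make_ar1(400, 0.5, seed = 20 + s)
    expect_equal(sample_entropy(x, 2, 0.2 * sd(x)),
                 pracma::sample_entropy(x, edim = 2, r = 0.2 * sd(x)))
  }
  # stronger regularity lowers entropy
  expect_lt(sample_entropy(make_ar1(800, 0.9, seed = 31)),
            sample_entropy(withr::with_seed(32, rnorm(800))))
})

test_that("permutation entropy spans its range and statav matches theory", {
  # strictly monotone series: a single ordinal pattern
  expect_equal(permutation_entropy(seq_len(200) + 0), 0)
  w <- withr::with_seed(12, rnorm(5000))
  expect_equal(permutation_entropy(w), log(6), tolerance = 0.05)
  # stationary white noise: sd of 5 segment means / sd ~ 1/sqrt(180)
  vals <- vapply(1:10, function(s) {
    stat_av(withr::with_seed(40 + s, rnorm(900)))
  }, numeric(1))
  expect_equal(mean(vals), 1 / sqrt(180), tolerance = 0.5)
})

test_that("extract_features covers the catalogue deterministically", {
  catalog <- feature_catalog()
  expect_gte(nrow(catalog), 30)
  expect_equal(anyDuplicated(catalog$feature_id), 0)
  fam <- c("distribution", "autocorrelation", "automutual-information",
           "spectral", "ar-model", "fluctuation", "entropy", "stationarity",
           "outlier")
  expect_setequal(unique(catalog$family), fam)

  x <- make_ar1(900, 0.4, seed = 13)
  f1 <- extract_features(x)
  f2 <- extract_features(x)
  expect_identical(f1, f2)
  expect_equal(f1$feature_id, catalog$feature_id)
  expect_error(extract_features(rnorm(100)), "128")
})

test_that("Yule-Walker AR(2) fit is consistent on an AR(1) source", {
  x <- make_ar1(5e4, 0.5, seed = 14)
  f <- extract_features(x)
  v <- setNames(f$value, f$feature_id)
  expect_equal(unname(v["ar2_phi1"]), 0.5, tolerance = 0.05 / 0.5)
  expect_equal(unname(v["ar2_phi2"]), 0, tolerance = 0.05)
})

test_that("non-distribution features are affine invariant, flags mark degenerate input", {
  x <- make_ar1(900, 0.3, seed = 15)
  f1 <- extract_features(x)
  f2 <- extract_features(3 * x - 5)
  nd <- f1$family != "distribution"
  expect_equal(f1$value[nd], f2$value[nd], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f1$value[!nd], f2$value[!nd])))

  fc <- extract_features(rep(1.5, 200))
  vc <- setNames(fc$finite, fc$feature_id)
  expect_true(vc[["mean"]] && vc[["median"]])
  expect_false(any(vc[fc$family %in% c("autocorrelation", "entropy",
                                       "automutual-information")]))
})

test_that("stronger AR(1) coefficients raise autocorrelation-family features", {
  phis <- c(0.2, 0.5, 0.8)
  stats <- vapply(seq_along(phis), function(i) {
    x <- make_ar1(5000, phis[i], seed = 50 + i)
    c(acf_lag(x, 1), ac_decay_time(x), low_freq_power_fraction(x))
  }, numeric(3))
  expect_true(all(diff(stats[1, ]) > 0)) # AC(1)
  expect_true(all(diff(stats[2, ]) > 0)) # decay time
  expect_true(all(diff(stats[3, ]) > 0)) # low-frequency power
})

test_that("feature_matrix computes per-key rows in catalogue order", {
  coh <- generate_cohort(tiny_config(n_rois = 2, seed = 3,
                                     group_sizes = c(control = 3, excitation = 3)))
  fm <- feature_matrix(coh$timeseries)
  expect_equal(nrow(fm), 6 * 2 * 2 * nrow(feature_catalog()))
  expect_true(all(c("animal", "group", "roi", "period", "feature_id",
                    "value", "finite") %in% names(fm)))
  expect_error(feature_matrix(dplyr::select(coh$timeseries, -"period")),
               "lacks columns")
})
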