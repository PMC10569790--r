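test_that("configuration invariants are enforced", {
  expect_error(synth_config(group_sizes = c(a = 2, b = 5)), ">= 3")
  expect_error(synth_config(phi0 = 0.9,
                            delta_phi = tibble::tibble(
                              group = "excitation", roi = "ROI1",
                              delta_phi = 0.2)),
               "non-stationary")
  expect_error(synth_config(session_length = 1500), "timeline")
  bad_c <- matrix(0.99, 2, 2); diag(bad_c) <- 1
  bad_c[1, 2] <- -0.99 # asymmetric
  expect_error(synth_config(
    rois = tibble::tibble(roi = c("A", "B"), category = c("seed", "cortical"),
                          rank = c(NA, 1L)),
    innovation_corr = list(control = list(baseline = bad_c, post = bad_c))))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- tiny_config(n_rois = 2, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$timeseries, c2$timeseries)
  c3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(c1$timeseries$value, c3$timeseries$value))
})

test_that("cohort layout matches the session design", {
  cfg <- tiny_config(n_rois = 2, seed = 7,
                     group_sizes = c(control = 3, excitation = 3))
  coh <- generate_cohort(cfg)
  counts <- dplyr::count(coh$timeseries, animal, roi, period)
  expect_true(all(counts$n == cfg$period_length))
  expect_equal(nrow(counts), 6 * 2 * 2) # animals x rois x periods
  expect_setequal(unique(coh$timeseries$period), c("baseline", "post"))
})

test_that("unfiltered AR(1) output has the configured lag-1 autocorrelation", {
  cfg <- synth_config(group_sizes = c(control = 10, excitation = 10),
                      phi0 = 0.6, phi_jitter_sd = 0, bandpass = FALSE,
                      seed = 8)
  coh <- generate_cohort(cfg)
  ac1 <- coh$timeseries |>
    dplyr::filter(period == "post") |>
    dplyr::group_by(animal) |>
    dplyr::summarise(ac = acf_lag(value, 1), .groups = "drop")
  expect_equal(mean(ac1$ac), 0.6, tolerance = 0.02 / 0.6)
})

test_that("larger coefficient shifts produce larger AC(1) changes, with and without filtering", {
  mean_delta_ac1 <- function(dphi, bandpass) {
    cfg <- tiny_config(
      n_rois = 1, seed = 9, group_sizes = c(control = 3, excitation = 6),
      delta_phi = tibble::tibble(group = "excitation", roi = "R1",
                                 delta_phi = dphi),
      bandpass = bandpass)
    coh <- generate_cohort(cfg)
    d <- coh$timeseries |>
      dplyr::filter(group == "excitation") |>
      dplyr::group_by(animal, period) |>
      dplyr::summarise(ac = acf_lag(value, 1), .groups = "drop") |>
      tidyr::pivot_wider(names_from = period, values_from = ac)
    mean(d$post - d$baseline)
  }
  raw <- vapply(c(0, 0.2, 0.4), mean_delta_ac1, numeric(1), bandpass = FALSE)
  expect_true(all(diff(raw) > 0))
  filt <- vapply(c(0, 0.2, 0.4), mean_delta_ac1, numeric(1), bandpass = TRUE)
  expect_true(all(diff(filt) > 0)) # band-pass preserves the ordering
})

test_that("baseline statistics are group-exchangeable by construction", {
  # classification on baseline-only features should hover at chance
  bcas <- vapply(1:3, function(s) {
    cfg <- reference_scenario(seed = 40 + s)
    cfg$rois <- cfg$rois[cfg$rois$roi == "CPdm", ]
    cfg$delta_phi <- cfg$delta_phi[cfg$delta_phi$roi == "CPdm", ]
    cfg$innovation_corr <- NULL
    cfg$behavior <- NULL
    coh <- generate_cohort(cfg)
    fm <- feature_matrix(dplyr::filter(coh$timeseries,
                                       group %in% c("control", "excitation")))
    base <- dplyr::filter(fm, period == "baseline") |>
      dplyr::mutate(delta = value) |>
      dplyr::select(animal, group, roi, feature_id, delta)
    base <- dplyr::filter(base, feature_id %in% well_behaved_mask(base))
    dm <- bolddyn:::delta_matrix(suppressWarnings(normalize_features(base)),
                                 "CPdm")
    repeated_cv_bca(dm$X, dm$group, n_repeats = 3, seed = s)$bca_mean
  }, numeric(1))
  expect_equal(mean(bcas), 50, tolerance = 12 / 50)
})

test_that("reference scenario wiring matches its documentation", {
  cfg <- reference_scenario()
  expect_equal(unname(cfg$group_sizes),
               c(10, 13, 15)) # control, excitation, inhibition
  expect_equal(sum(cfg$rois$category == "thalamic-loop"), 6)
  expect_equal(sum(cfg$rois$category == "thalamic-nonloop"), 8)
  expect_equal(sort(cfg$rois$rank[cfg$rois$category == "cortical"]), 1:12)
  dp <- cfg$delta_phi
  expect_equal(unique(dp$delta_phi[dp$group == "excitation" &
                                     dp$roi == "CPdm"]), 0.2)
  expect_equal(unique(dp$delta_phi[dp$group == "inhibition" &
                                     dp$roi == "PF"]), 0.1)
  # cortical shift grows linearly with hierarchy rank
  cort <- dp[dp$group == "excitation" &
               dp$roi %in% cfg$rois$roi[cfg$rois$category == "cortical"], ]
  rk <- cfg$rois$rank[match(cort$roi, cfg$rois$roi)]
  expect_equal(cort$delta_phi, 0.2 * rk / 12)
  # excitation drops seed-cortical coupling, inhibition raises it
  ex <- cfg$innovation_corr$excitation
  expect_equal(unname(ex$baseline["CPdm", "MOp"]), 0.5)
  expect_equal(unname(ex$post["CPdm", "MOp"]), 0.2)
  expect_equal(unname(cfg$innovation_corr$inhibition$post["CPdm", "MOp"]), 0.65)
})

test_that("behavior is coupled to realized delta-FC", {
  cfg <- reference_scenario(seed = 12)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$behavior), 38)
  fcs <- fc_summary(fc_per_minute(coh$timeseries, "CPdm",
                                  targets = cfg$behavior$edges))
  per_animal <- fcs |>
    dplyr::group_by(animal) |>
    dplyr::summarise(dfc = mean(delta_fc), .groups = "drop") |>
    dplyr::inner_join(coh$behavior, by = "animal")
  expect_gt(pearson_r(per_animal$dfc, per_animal$rotation_asymmetry), 0.5)
})
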