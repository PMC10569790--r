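#' Synthetic cohort configuration
#'
#' Defines a cohort of animals whose regional BOLD signals are simulated as a
#' multivariate AR(1) process with a diagonal transition (one autoregressive
#' coefficient per ROI) and correlated Gaussian innovations. Chemogenetic
#' modulation is emulated by adding `delta_phi` to a ROI's coefficient after
#' the injection index (raising its lag-1 autocorrelation and low-frequency
#' power) and by switching the innovation-correlation matrix (changing
#' pairwise functional connectivity). The session timeline mirrors the
#' acquisition design: `session_length` samples at 1 Hz, baseline = the first
#' `period_length` samples, injection at `injection_index`, `post_skip`
#' samples discarded for drug onset, then `period_length` post samples.
#'
#' @param group_sizes Named integer vector of animals per group
#'   (default `c(control = 10, excitation = 13, inhibition = 15)`).
#' @param rois Tibble with columns `roi`, `category` (one of `seed`,
#'   `thalamic-loop`, `thalamic-nonloop`, `cortical`) and `rank` (integer
#'   hierarchy rank for cortical ROIs, `NA` otherwise).
#' @param session_length,injection_index,post_skip,period_length Session
#'   timeline in samples (defaults 2280, 900, 240, 900; sampling interval
#'   1 s).
#' @param phi0 Baseline AR(1) coefficient: scalar or named vector per ROI
#'   (default 0.3).
#' @param delta_phi Tibble `group`, `roi`, `delta_phi` of post-injection
#'   coefficient shifts; missing combinations default to 0.
#' @param innovation_corr Named list per group, each a list with elements
#'   `baseline` and `post` (ROI x ROI positive-definite correlation
#'   matrices); `NULL` means uncorrelated innovations throughout.
#' @param phi_jitter_sd Between-animal SD of the per-ROI coefficient
#'   (default 0.05).
#' @param bandpass Apply a zero-phase order-2 Butterworth band-pass
#'   (default TRUE) over `band` (Hz, default 0.01-0.25).
#' @param band Band-pass edges in Hz.
#' @param behavior `NULL`, or a list with `edges` (target ROI labels whose
#'   seed-edge delta-FC drives behavior), `intercept`, `slope`, `noise_sd`:
#'   rotation asymmetry is `intercept + slope * mean(delta_fc) + noise`.
#' @param seed Master seed.
#' @return A `synth_config` object (validated list).
#' @export
synth_config <- function(group_sizes = c(control = 10, excitation = 13,
                                         inhibition = 15),
                         rois = tibble::tibble(roi = "ROI1", category = "seed",
                                               rank = NA_integer_),
                         session_length = 2280, injection_index = 900,
                         post_skip = 240, period_length = 900,
                         phi0 = 0.3, delta_phi = NULL, innovation_corr = NULL,
                         phi_jitter_sd = 0.05, bandpass = TRUE,
                         band = c(0.01, 0.25), behavior = NULL, seed = 1) {
  if (any(group_sizes < 3)) stop("group sizes must be >= 3", call. = FALSE)
  if (is.null(names(group_sizes))) stop("group_sizes must be named", call. = FALSE)
  stopifnot(all(c("roi", "category") %in% names(rois)))
  if (injection_index + post_skip + period_length > session_length ||
      period_length > injection_index) {
    stop("session timeline is inconsistent", call. = FALSE)
  }
  r <- rois$roi
  phi0_vec <- if (length(phi0) == 1) setNames(rep(phi0, length(r)), r) else phi0[r]
  if (anyNA(phi0_vec)) stop("phi0 must cover every ROI", call. = FALSE)
  if (is.null(delta_phi)) {
    delta_phi <- tibble::tibble(group = character(), roi = character(),
                                delta_phi = numeric())
  }
  for (g in names(group_sizes)) {
    dp <- delta_phi_vector(delta_phi, g, r)
    if (any(abs(phi0_vec + dp) >= 1)) {
      stop("non-stationary configuration: |phi0 + delta_phi| must be < 1",
           call. = FALSE)
    }
  }
  if (!is.null(innovation_corr)) {
    for (g in names(innovation_corr)) {
      for (per in c("baseline", "post")) {
        C <- innovation_corr[[g]][[per]]
        stopifnot(isTRUE(all.equal(C, t(C))), all(diag(C) == 1))
        tryCatch(chol(C), error = function(e) {
          stop("innovation correlation for group '", g, "' (", per,
               ") is not positive definite", call. = FALSE)
        })
      }
    }
  }
  structure(
    list(group_sizes = group_sizes, rois = rois,
         session_length = session_length, injection_index = injection_index,
         post_skip = post_skip, period_length = period_length,
         phi0 = phi0_vec, delta_phi = delta_phi,
         innovation_corr = innovation_corr, phi_jitter_sd = phi_jitter_sd,
         bandpass = bandpass, band = band, behavior = behavior, seed = seed),
    class = "synth_config"
  )
}

# delta_phi lookup as a named vector over rois for one group
delta_phi_vector <- function(delta_phi, group, rois) {
  out <- setNames(rep(0, length(rois)), rois)
  d <- delta_phi[delta_phi$group == group, ]
  out[d$roi] <- d$delta_phi
  out
}

#' Generate a synthetic cohort
#'
#' Simulates every animal's multi-ROI session from a [synth_config()]:
#' per-animal AR coefficients (`phi0` plus Gaussian jitter), correlated
#' innovations switching from the baseline to the post correlation matrix at
#' the injection index, coefficient shifts `delta_phi` after injection, an
#' optional zero-phase band-pass, slicing into baseline and post periods, and
#' (optionally) behavior generated from each animal's realized delta-FC.
#' Fully reproducible from the seed.
#'
#' @param config A `synth_config` object.
#' @param seed Integer seed (defaults to the config's).
#' @return Object of class `synth_cohort`: list with `timeseries` (long
#'   tibble: `animal`, `group`, `roi`, `period`, `t`, `value`), `animals`,
#'   `rois`, `behavior` (tibble or `NULL`), `config`, `seed`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  rois <- config$rois$roi
  R <- length(rois)
  burn <- 200L
  total <- burn + config$session_length
  switch_at <- burn + config$injection_index # innovations/phi switch after this
  post_start <- config$injection_index + config$post_skip + 1L
  post_end <- post_start + config$period_length - 1L

  groups <- rep(names(config$group_sizes), config$group_sizes)
  animals <- sprintf("m%02d", seq_along(groups))

  chol_of <- function(g, per) {
    if (is.null(config$innovation_corr) ||
        is.null(config$innovation_corr[[g]])) return(diag(R))
    chol(config$innovation_corr[[g]][[per]])
  }

  withr::with_seed(seed, {
    sim <- purrr::map2(animals, groups, function(a, g) {
      phi_b <- config$phi0 + rnorm(R, 0, config$phi_jitter_sd)
      phi_b <- pmin(pmax(phi_b, -0.98), 0.98)
      phi_p <- phi_b + delta_phi_vector(config$delta_phi, g, rois)
      phi_p <- pmin(pmax(phi_p, -0.98), 0.98)

      Z <- matrix(rnorm(total * R), total, R)
      eps <- rbind(Z[seq_len(switch_at), , drop = FALSE] %*% chol_of(g, "baseline"),
                   Z[(switch_at + 1):total, , drop = FALSE] %*% chol_of(g, "post"))
      X <- matrix(0, total, R)
      for (j in seq_len(R)) {
        xb <- stats::filter(eps[seq_len(switch_at), j], phi_b[j],
                            method = "recursive")
        xp <- stats::filter(eps[(switch_at + 1):total, j], phi_p[j],
                            method = "recursive", init = xb[switch_at])
        X[, j] <- c(xb, xp)
      }
      X <- X[(burn + 1):total, , drop = FALSE]
      if (config$bandpass) {
        bf <- signal::butter(2, config$band * 2, type = "pass")
        X <- apply(X, 2, function(col) signal::filtfilt(bf, col))
      }
      pl <- config$period_length
      tibble::tibble(
        animal = a, group = g,
        roi = rep(rois, each = 2L * pl),
        period = rep(rep(c("baseline", "post"), each = pl), R),
        t = rep(c(seq_len(pl), seq_len(pl)), R),
        value = as.numeric(vapply(seq_len(R), function(j) {
          c(X[seq_len(pl), j], X[post_start:post_end, j])
        }, numeric(2L * pl)))
      )
    })
    ts_long <- dplyr::bind_rows(sim)

    behavior <- NULL
    if (!is.null(config$behavior)) {
      b <- config$behavior
      seed_roi <- config$rois$roi[config$rois$category == "seed"][1]
      fcs <- fc_summary(fc_per_minute(ts_long, seed_roi, targets = b$edges))
      per_animal <- fcs |>
        dplyr::group_by(.data$animal) |>
        dplyr::summarise(dfc = mean(.data$delta_fc), .groups = "drop")
      behavior <- tibble::tibble(
        animal = per_animal$animal,
        rotation_asymmetry = b$intercept + b$slope * per_animal$dfc +
          rnorm(nrow(per_animal), 0, b$noise_sd)
      )
    }

    structure(
      list(timeseries = ts_long,
           animals = tibble::tibble(animal = animals, group = groups),
           rois = config$rois, behavior = behavior, config = config,
           seed = seed),
      class = "synth_cohort"
    )
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals (%s), %d ROIs, %d samples/period\n",
              nrow(x$animals),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", "),
              nrow(x$rois), x$config$period_length))
  invisible(x)
}

#' Reference simulation scenario with loop, hierarchy and coupling effects
#'
#' A documented default configuration reproducing the qualitative effect
#' pattern of striatal D1 excitation/inhibition: post-injection
#' autocorrelation increases of +0.2 (excitation) / +0.1 (inhibition) in the
#' seed and the six reciprocally connected ("loop") thalamic ROIs, none in the
#' eight non-loop thalamic ROIs, cortical effects growing linearly with the
#' unimodal hierarchy rank (rank/12 of the full effect), and seed-cortical
#' innovation coupling on three edges dropping from 0.5 to 0.2 under
#' excitation and rising to 0.65 under inhibition, on top of a global
#' equicorrelation of 0.2. Behavior (rotation asymmetry) is generated from
#' each animal's realized delta-FC on the perturbed edges.
#'
#' @param seed Master seed.
#' @return A `synth_config`.
#' @export
reference_scenario <- function(seed = 1) {
  rois <- tibble::tibble(
    roi = c("CPdm",
            "PF", "MD", "LD", "LP", "VM|CM", "VAL|VPM|VPMpc",
            "VPL", "RE|LH|RH", "PO|POL", "SPF|SPA|PP", "IMD", "RT", "AM", "CL",
            "PL", "ILA", "ORBl", "ACAd", "RSPv", "TEa",
            "VISam", "AUDp", "VISp", "SSs", "SSp-bfd", "MOp"),
    category = c("seed", rep("thalamic-loop", 6), rep("thalamic-nonloop", 8),
                 rep("cortical", 12)),
    rank = c(rep(NA_integer_, 15), 1:12)
  )
  groups <- c("control", "excitation", "inhibition")
  eff <- c(control = 0, excitation = 0.2, inhibition = 0.1)
  delta_phi <- purrr::map_dfr(groups[-1], function(g) {
    dplyr::bind_rows(
      tibble::tibble(group = g,
                     roi = rois$roi[rois$category %in% c("seed", "thalamic-loop")],
                     delta_phi = eff[[g]]),
      tibble::tibble(group = g,
                     roi = rois$roi[rois$category == "cortical"],
                     delta_phi = eff[[g]] * rois$rank[rois$category == "cortical"] / 12)
    )
  })

  R <- nrow(rois)
  edges <- c("MOp", "SSp-bfd", "ACAd")
  base_c <- matrix(0.2, R, R, dimnames = list(rois$roi, rois$roi))
  diag(base_c) <- 1
  base_c["CPdm", edges] <- base_c[edges, "CPdm"] <- 0.5
  post_c <- list(control = base_c, excitation = base_c, inhibition = base_c)
  post_c$excitation["CPdm", edges] <- post_c$excitation[edges, "CPdm"] <- 0.2
  post_c$inhibition["CPdm", edges] <- post_c$inhibition[edges, "CPdm"] <- 0.65
  innovation_corr <- lapply(setNames(groups, groups), function(g) {
    list(baseline = base_c, post = post_c[[g]])
  })

  synth_config(
    rois = rois, delta_phi = delta_phi, innovation_corr = innovation_corr,
    behavior = list(edges = edges, intercept = 0, slope = 120, noise_sd = 8),
    seed = seed
  )
}

#' Null scenario (no group effect)
#'
#' Convenience configuration with `delta_phi = 0` everywhere and a constant
#' innovation correlation, used for calibration: any classifier's balanced
#' accuracy has expectation 50% and permutation p-values are uniform.
#'
#' @param n_rois Number of ROIs (default 1).
#' @param group_sizes Named group sizes (default control 10 vs excitation 13).
#' @param seed Master seed.
#' @return A `synth_config`.
#' @export
null_scenario <- function(n_rois = 1,
                          group_sizes = c(control = 10, excitation = 13),
                          seed = 1) {
  synth_config(
    group_sizes = group_sizes,
    rois = tibble::tibble(
      roi = if (n_rois == 1) "ROI1" else sprintf("ROI%02d", seq_len(n_rois)),
      category = c("seed", rep("thalamic-nonloop", n_rois - 1)),
      rank = NA_integer_
    ),
    seed = seed
  )
}

#' Write a cohort to plain-text files
#'
#' Writes `timeseries.tsv` (long format: `animal`, `group`, `roi`, `period`,
#' `t`, `value`) and, when present, `behavior.tsv`, plus `config.json`
#' provenance, into a directory.
#'
#' @param cohort A `synth_cohort` (or any list with a `timeseries` tibble).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts_out <- dplyr::mutate(cohort$timeseries,
                          value = sprintf("%.17g", .data$value))
  readr::write_tsv(ts_out, file.path(dir, "timeseries.tsv"))
  if (!is.null(cohort$behavior)) {
    readr::write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  }
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$innovation_corr <- lapply(cfg$innovation_corr, lapply, as.matrix)
    jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Read a cohort from plain-text files
#'
#' @param dir Directory written by [write_cohort()], or a path to a single
#'   long-format time-series table.
#' @return List with `timeseries` and (if present) `behavior` tibbles.
#' @export
read_cohort <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "timeseries.tsv") else dir
  ts <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          animal = "c", group = "c", roi = "c", period = "c",
                          t = "i", value = "c"))
  # base R numeric conversion round-trips %.17g exactly
  ts$value <- as.numeric(ts$value)
  beh_path <- file.path(dirname(path), "behavior.tsv")
  behavior <- if (file.exists(beh_path)) {
    readr::read_tsv(beh_path, show_col_types = FALSE)
  } else NULL
  list(timeseries = ts, behavior = behavior)
}
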