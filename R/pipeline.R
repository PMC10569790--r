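#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. `smoke = TRUE` switches
#' to reduced resampling settings (5 CV repeats, 200 permutations) for quick,
#' fully deterministic runs; the full settings (50 repeats, 5000 permutations)
#' reproduce study-scale inference.
#'
#' @param input A `synth_config` (cohort is generated), a `synth_cohort`, a
#'   path readable by [read_cohort()], or a list with a `timeseries` tibble.
#' @param contrasts List of group contrasts `c(reference, stimulation)`.
#' @param catalog Feature catalogue (default [feature_catalog()]).
#' @param n_folds,n_repeats CV settings (defaults 10, 50).
#' @param n_perm Permutations for all permutation tests (default 5000).
#' @param fdr_level FDR significance level for region classification and FC
#'   contrasts (default 0.05).
#' @param top_p_fdr,top_n Feature-score top-set selection (defaults 0.01, 100).
#' @param n_perm_fc Permutations for the functional-connectivity group
#'   tests (default 5000). Kept at full resolution even in smoke mode: the FC
#'   permutation statistic is a difference of means (microseconds per
#'   permutation), and p-value granularity of 1/(B+1) would otherwise limit
#'   FDR resolution across the many ROI pairs.
#' @param fc_window FC window length in samples (default 60).
#' @param out_dir Output directory for result tables (`NULL`: no files).
#' @param seed Master seed; every stage derives its randomness from it.
#' @param smoke Reduced resampling mode (default FALSE).
#' @return A `run_config` list.
#' @export
run_config <- function(input,
                       contrasts = list(c("control", "excitation"),
                                        c("control", "inhibition")),
                       catalog = feature_catalog(), n_folds = 10,
                       n_repeats = 50, n_perm = 5000, n_perm_fc = 5000,
                       fdr_level = 0.05,
                       top_p_fdr = 0.01, top_n = 100, fc_window = 60,
                       out_dir = NULL, seed = 1, smoke = FALSE) {
  if (smoke) {
    n_repeats <- 5
    n_perm <- 200
  }
  structure(
    list(input = input, contrasts = contrasts, catalog = catalog,
         n_folds = n_folds, n_repeats = n_repeats, n_perm = n_perm,
         n_perm_fc = n_perm_fc, fdr_level = fdr_level, top_p_fdr = top_p_fdr,
         top_n = top_n, fc_window = fc_window, out_dir = out_dir, seed = seed,
         smoke = smoke),
    class = "run_config"
  )
}

#' Validate a long-format cohort table
#'
#' Schema and sanity checks for the pipeline's input: required columns,
#' finite values, per-(animal, ROI, period) sample counts, and (optionally)
#' known group labels. Never mutates the data.
#'
#' @param x A data frame, a `synth_cohort`, or a file/directory path.
#' @param expected_samples Samples expected per (animal, ROI, period)
#'   (default 900).
#' @param groups Known group labels (`NULL` skips the check).
#' @return Tibble of issues (`check`, `key`, `detail`); zero rows when the
#'   table is well formed.
#' @export
validate_input <- function(x, expected_samples = 900, groups = NULL) {
  ts <- if (is.character(x)) read_cohort(x)$timeseries
        else if (inherits(x, "synth_cohort")) x$timeseries
        else if (is.list(x) && !is.data.frame(x)) x$timeseries
        else x
  issues <- list()
  required <- c("animal", "group", "roi", "period", "t", "value")
  missing_cols <- setdiff(required, names(ts))
  if (length(missing_cols)) {
    return(tibble::tibble(check = "columns", key = missing_cols,
                          detail = "required column missing"))
  }
  bad_period <- setdiff(unique(ts$period), c("baseline", "post"))
  if (length(bad_period)) {
    issues <- c(issues, list(tibble::tibble(
      check = "period", key = bad_period, detail = "unknown period label")))
  }
  if (!is.null(groups)) {
    bad_group <- setdiff(unique(ts$group), groups)
    if (length(bad_group)) {
      issues <- c(issues, list(tibble::tibble(
        check = "group", key = bad_group, detail = "unknown group label")))
    }
  }
  nonfinite <- which(!is.finite(ts$value))
  if (length(nonfinite)) {
    issues <- c(issues, list(tibble::tibble(
      check = "finite", key = as.character(head(nonfinite, 20)),
      detail = "non-finite value at row")))
  }
  counts <- ts |>
    dplyr::count(.data$animal, .data$roi, .data$period) |>
    dplyr::filter(.data$n != expected_samples)
  if (nrow(counts)) {
    issues <- c(issues, list(tibble::tibble(
      check = "samples",
      key = paste(counts$animal, counts$roi, counts$period, sep = "/"),
      detail = sprintf("%d samples (expected %d)", counts$n, expected_samples))))
  }
  if (length(issues)) dplyr::bind_rows(issues)
  else tibble::tibble(check = character(), key = character(),
                      detail = character())
}

#' Run the full analysis pipeline
#'
#' Executes feature extraction, baseline subtraction, robust normalization,
#' per-ROI classification with permutation significance and FDR across ROIs
#' (per contrast), the loop versus non-loop accuracy comparison and the
#' cortical-hierarchy correlation when ROI categories/ranks are available,
#' feature-level scoring and clustering for the best-classified ROI, and the
#' windowed functional-connectivity analysis from the seed ROI. All
#' randomness derives from `config$seed`; rerunning with the same config
#' reproduces every number.
#'
#' @param config A [run_config()].
#' @return Object of class `bolddyn_run`: list with `classification`,
#'   `loop_test` (per contrast), `hierarchy` (per contrast), `feature_scores`,
#'   `feature_clusters`, `fc_minutes`, `fc_summary`, `baseline_fc`,
#'   `delta_fc_test`, `behavior_cor`, `validation`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  cohort <- resolve_input(config$input)
  ts_long <- cohort$timeseries
  rois_meta <- cohort$rois

  validation <- validate_input(ts_long,
                               expected_samples = length(unique(ts_long$t)))
  if (nrow(validation) > 0) {
    stop("input validation failed; first issue: ",
         validation$check[1], " [", validation$key[1], "] ",
         validation$detail[1], call. = FALSE)
  }
  missing_groups <- setdiff(unique(unlist(config$contrasts)),
                            unique(ts_long$group))
  if (length(missing_groups)) {
    stop("contrast group(s) absent from data: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }

  features <- feature_matrix(ts_long, config$catalog)
  delta <- delta_features(features)

  classification <- purrr::map_dfr(config$contrasts, function(ct) {
    classify_regions(delta, contrast = ct, n_perm = config$n_perm,
                     n_folds = config$n_folds, n_repeats = config$n_repeats,
                     fdr_level = config$fdr_level, seed = config$seed)
  })

  loop_test <- NULL
  hierarchy <- NULL
  if (!is.null(rois_meta) && "category" %in% names(rois_meta)) {
    loop_rois <- rois_meta$roi[rois_meta$category == "thalamic-loop"]
    nonloop_rois <- rois_meta$roi[rois_meta$category == "thalamic-nonloop"]
    if (length(loop_rois) && length(nonloop_rois)) {
      loop_test <- lapply(split_contrasts(classification), function(cl) {
        compare_bca_sets(cl$bca_mean[cl$roi %in% loop_rois],
                         cl$bca_mean[cl$roi %in% nonloop_rois])
      })
    }
    cort <- rois_meta[rois_meta$category == "cortical" & !is.na(rois_meta$rank), ]
    if (nrow(cort) >= 5) {
      hierarchy <- lapply(split_contrasts(classification), function(cl) {
        bca <- setNames(cl$bca_mean, cl$roi)
        hierarchy_correlation(bca, setNames(cort$rank, cort$roi))
      })
    }
  }

  best <- classification |>
    dplyr::arrange(dplyr::desc(.data$bca_mean)) |>
    dplyr::slice(1)
  best_contrast <- strsplit(best$contrast, "-vs-", fixed = TRUE)[[1]]
  fscores <- score_features(delta, best$roi, best_contrast)
  top <- select_top_features(fscores, n = config$top_n,
                             p_fdr_max = config$top_p_fdr)
  fclusters <- if (length(top) >= 2) {
    cluster_top_features(delta, roi = best$roi, features = top)
  } else NULL

  seed_roi <- if (!is.null(rois_meta) && any(rois_meta$category == "seed")) {
    rois_meta$roi[rois_meta$category == "seed"][1]
  } else unique(ts_long$roi)[1]
  fc_min <- fc_per_minute(ts_long, seed_roi, window = config$fc_window)
  fcs <- fc_summary(fc_min)
  baseline_fc <- baseline_fc_test(fcs)
  delta_fc <- group_delta_fc_test(fcs, config$contrasts,
                                  n_perm = config$n_perm_fc,
                                  fdr_level = config$fdr_level,
                                  seed = config$seed)
  behavior_cor <- NULL
  if (!is.null(cohort$behavior)) {
    behavior_cor <- purrr::map_dfr(unique(fcs$target), function(tg) {
      behavior_fc_correlation(cohort$behavior, fcs, tg)
    })
  }

  res <- structure(
    list(classification = classification, loop_test = loop_test,
         hierarchy = hierarchy, feature_scores = fscores,
         feature_clusters = fclusters, fc_minutes = fc_min, fc_summary = fcs,
         baseline_fc = baseline_fc, delta_fc_test = delta_fc,
         behavior_cor = behavior_cor, validation = validation,
         provenance = list(
           seed = config$seed, smoke = config$smoke,
           n_perm = config$n_perm, n_repeats = config$n_repeats,
           config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
           r_version = as.character(getRversion()),
           runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "bolddyn_run"
  )
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

split_contrasts <- function(classification) {
  split(classification, classification$contrast)
}

resolve_input <- function(input) {
  if (inherits(input, "synth_config")) return(generate_cohort(input))
  if (inherits(input, "synth_cohort")) return(input)
  if (is.character(input)) {
    rc <- read_cohort(input)
    return(list(timeseries = rc$timeseries, behavior = rc$behavior,
                rois = NULL))
  }
  if (is.list(input) && !is.null(input$timeseries)) {
    return(list(timeseries = input$timeseries, behavior = input$behavior,
                rois = input$rois))
  }
  stop("unsupported input; supply a synth_config, synth_cohort, path, or a ",
       "list with a 'timeseries' tibble", call. = FALSE)
}

# write result tables + machine-readable summary; every table carries the
# config hash as a header comment line
write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- res$provenance$config_hash
  wt <- function(tbl, name) {
    path <- file.path(dir, name)
    writeLines(paste0("# config_hash=", hash), path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  }
  wt(res$classification, "classification.tsv")
  wt(res$feature_scores, "feature_scores.tsv")
  wt(res$fc_summary, "fc_summary.tsv")
  wt(res$baseline_fc, "baseline_fc.tsv")
  wt(res$delta_fc_test, "delta_fc_test.tsv")
  if (!is.null(res$behavior_cor)) wt(res$behavior_cor, "behavior_cor.tsv")
  if (!is.null(res$feature_clusters)) {
    write_feature_tree(res$feature_clusters, file.path(dir, "feature_tree.nwk"))
  }
  summary <- list(
    provenance = res$provenance,
    n_significant_rois = sum(res$classification$significant),
    best_roi = res$classification$roi[which.max(res$classification$bca_mean)],
    loop_test = lapply(res$loop_test, function(l) {
      list(u = l$u_statistic, z = l$z_value, p_exact = l$p_exact,
           p_normal = l$p_normal)
    }),
    hierarchy = res$hierarchy
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' One-row summary of a pipeline run
#' @param x A `bolddyn_run` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.bolddyn_run <- function(x, ...) {
  tibble::tibble(
    n_rois = length(unique(x$classification$roi)),
    n_contrasts = length(unique(x$classification$contrast)),
    n_significant = sum(x$classification$significant),
    best_bca = max(x$classification$bca_mean),
    seed = x$provenance$seed,
    config_hash = x$provenance$config_hash
  )
}

#' @export
print.bolddyn_run <- function(x, ...) {
  cat("bolddyn pipeline run\n")
  cat(sprintf("  %d ROI x contrast classifications, %d significant (FDR)\n",
              nrow(x$classification), sum(x$classification$significant)))
  cat(sprintf("  best: %s (%s), BCA = %.1f%%\n",
              x$classification$roi[which.max(x$classification$bca_mean)],
              x$classification$contrast[which.max(x$classification$bca_mean)],
              max(x$classification$bca_mean)))
  invisible(x)
}
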