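#' Balanced classification accuracy
#'
#' Arithmetic mean of sensitivity and specificity (equivalently, the mean of
#' per-class recalls), in percent.
#'
#' @param true_labels Vector of true class labels (both classes must occur).
#' @param predicted_labels Vector of predicted labels, same length.
#' @return Percentage in \[0, 100\].
#' @examples
#' balanced_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "a"))
#' @export
balanced_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  classes <- unique(true_labels)
  if (length(classes) != 2) {
    stop("true_labels must contain exactly two classes", call. = FALSE)
  }
  recalls <- vapply(classes, function(cl) {
    mean(predicted_labels[true_labels == cl] == cl)
  }, numeric(1))
  100 * mean(recalls)
}

# balanced accuracy for integer codes 1/2 (internal, fast path)
bca_codes <- function(true_int, pred_int) {
  50 * (mean(pred_int[true_int == 1L] == 1L) +
          mean(pred_int[true_int == 2L] == 2L))
}

# stratified fold assignment: class-size-preserving, every class spread over
# as many folds as it has members
stratified_folds <- function(y_int, k) {
  folds <- integer(length(y_int))
  for (cl in c(1L, 2L)) {
    idx <- which(y_int == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Repeated stratified cross-validated balanced accuracy
#'
#' Mean k-fold stratified cross-validated balanced accuracy of a linear SVM
#' (inverse-probability class reweighting, fixed cost), averaged over
#' `n_repeats` fresh random partitions. Within one repeat, held-out
#' predictions are pooled across the k folds before the balanced accuracy is
#' computed, which remains well defined when single folds lack a class (small,
#' imbalanced cohorts force fold sizes of 1-3). Deterministic given `seed`.
#'
#' @param X Numeric matrix, animals x features (normalized deltas).
#' @param labels Two-class factor or vector, one entry per row of `X`.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Number of repeated partitions (default 50).
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer seed controlling all partitions.
#' @return List with `bca_mean` and `bca_repeats` (length `n_repeats`).
#' @export
repeated_cv_bca <- function(X, labels, n_folds = 10, n_repeats = 50,
                            cost = 1, seed = 1) {
  X <- as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  y_int <- as.integer(y)
  if (min(tabulate(y_int, 2)) < 2) {
    stop("need at least 2 animals per class", call. = FALSE)
  }
  bca_repeats <- withr::with_seed(seed, {
    vapply(seq_len(n_repeats), function(rep_i) {
      cv_bca_once(X, y_int, n_folds, cost)
    }, numeric(1))
  })
  list(bca_mean = mean(bca_repeats), bca_repeats = bca_repeats)
}

# one stratified k-fold pass; pooled held-out predictions
cv_bca_once <- function(X, y_int, n_folds, cost) {
  for (attempt in 1:25) {
    folds <- stratified_folds(y_int, n_folds)
    ok <- all(vapply(unique(folds), function(f) {
      length(unique(y_int[folds != f])) == 2L
    }, logical(1)))
    if (ok) break
    if (attempt == 25) stop("could not build folds with two-class training sets",
                            call. = FALSE)
  }
  pred <- integer(length(y_int))
  for (f in unique(folds)) {
    te <- folds == f
    pred[te] <- svm_fit_predict(X[!te, , drop = FALSE], y_int[!te],
                                X[te, , drop = FALSE], cost)
  }
  bca_codes(y_int, pred)
}

#' Permutation significance of a region's classification accuracy
#'
#' Builds the null distribution of the mean cross-validated balanced accuracy
#' by rerunning the identical CV procedure (same internal seed, hence paired
#' partitions) under class-size-preserving permutations of the group labels,
#' and computes the one-sided add-one permutation p-value.
#'
#' @inheritParams repeated_cv_bca
#' @param n_perm Number of label permutations (default 5000).
#' @return Object of class `region_perm_test`: list with `bca_mean`,
#'   `bca_repeats`, `null_bcas`, `p_perm`, `n1`, `n2`. Use [tidy()] /
#'   [glance()].
#' @export
region_permutation_test <- function(X, labels, n_perm = 5000, n_folds = 10,
                                    n_repeats = 50, cost = 1, seed = 1) {
  X <- as.matrix(X)
  y <- factor(labels)
  y_int <- as.integer(y)
  obs <- repeated_cv_bca(X, y, n_folds = n_folds, n_repeats = n_repeats,
                         cost = cost, seed = seed)
  perms <- withr::with_seed(seed + 1L, {
    replicate(n_perm, sample(y_int), simplify = FALSE)
  })
  null_bcas <- vapply(perms, function(yb) {
    withr::with_seed(seed, {
      mean(vapply(seq_len(n_repeats), function(i) {
        cv_bca_once(X, yb, n_folds, cost)
      }, numeric(1)))
    })
  }, numeric(1))
  structure(
    list(bca_mean = obs$bca_mean, bca_repeats = obs$bca_repeats,
         null_bcas = null_bcas, p_perm = perm_pvalue(obs$bca_mean, null_bcas),
         n1 = sum(y_int == 1L), n2 = sum(y_int == 2L)),
    class = "region_perm_test"
  )
}

#' @export
print.region_perm_test <- function(x, ...) {
  cat(sprintf("Region permutation test: BCA = %.1f%% (n = %d + %d), p = %.4g (B = %d)\n",
              x$bca_mean, x$n1, x$n2, x$p_perm, length(x$null_bcas)))
  invisible(x)
}

#' Tidy per-repeat balanced accuracies
#' @param x A `region_perm_test` object.
#' @param ... Unused.
#' @return Tibble with one row per CV repeat.
#' @export
tidy.region_perm_test <- function(x, ...) {
  tibble::tibble(repeat_id = seq_along(x$bca_repeats), bca = x$bca_repeats)
}

#' One-row summary of a region permutation test
#' @param x A `region_perm_test` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.region_perm_test <- function(x, ...) {
  tibble::tibble(bca_mean = x$bca_mean, p_perm = x$p_perm,
                 n_perm = length(x$null_bcas), n1 = x$n1, n2 = x$n2)
}

#' Classify every ROI for one group contrast
#'
#' For each ROI: normalizes the baseline-subtracted feature table (outlier-
#' robust sigmoid, both groups jointly), runs the repeated-CV linear SVM with
#' permutation significance, and corrects p-values across ROIs by the
#' Benjamini-Hochberg FDR.
#'
#' @param delta Delta-feature tibble from [delta_features()].
#' @param contrast Character vector of two group labels,
#'   `c(reference, stimulation)`.
#' @param rois ROIs to classify (default: all in `delta`).
#' @param fdr_level Significance level applied to FDR-corrected p-values
#'   (default 0.05).
#' @param normalize Either `"global"` (sigmoid fit once on the full delta
#'   matrix of the two groups; the default convention) or `"none"` (input
#'   already normalized).
#' @inheritParams region_permutation_test
#' @return Tibble with one row per ROI (`roi`, `contrast`, `bca_mean`,
#'   `p_perm`, `p_fdr`, `significant`, `n1`, `n2`); the per-ROI
#'   `region_perm_test` objects are attached as attribute `"tests"`.
#' @export
classify_regions <- function(delta, contrast, rois = NULL, n_perm = 5000,
                             n_folds = 10, n_repeats = 50, cost = 1,
                             fdr_level = 0.05, normalize = c("global", "none"),
                             seed = 1) {
  normalize <- match.arg(normalize)
  stopifnot(length(contrast) == 2)
  d <- dplyr::filter(delta, .data$group %in% contrast)
  if (!is.null(rois)) d <- dplyr::filter(d, .data$roi %in% rois)
  rois <- if (is.null(rois)) unique(d$roi) else rois
  mask <- well_behaved_mask(d)
  d <- dplyr::filter(d, .data$feature_id %in% mask)
  if (normalize == "global") d <- suppressWarnings(normalize_features(d))

  tests <- purrr::imap(setNames(rois, rois), function(r, nm) {
    dm <- delta_matrix(d, r, groups = contrast)
    keep <- colSums(!is.finite(dm$X)) == 0
    g <- factor(as.character(dm$group), levels = contrast)
    region_permutation_test(dm$X[, keep, drop = FALSE], g, n_perm = n_perm,
                            n_folds = n_folds, n_repeats = n_repeats,
                            cost = cost, seed = seed + match(nm, rois))
  })
  out <- purrr::map_dfr(tests, function(t) {
    tibble::tibble(bca_mean = t$bca_mean, p_perm = t$p_perm,
                   n1 = t$n1, n2 = t$n2)
  }, .id = "roi")
  out <- out |>
    dplyr::mutate(
      contrast = paste(contrast, collapse = "-vs-"),
      p_fdr = bh_fdr(.data$p_perm),
      significant = .data$p_fdr < fdr_level
    ) |>
    dplyr::select(dplyr::all_of(c("roi", "contrast", "bca_mean", "p_perm",
                                  "p_fdr", "significant", "n1", "n2")))
  attr(out, "tests") <- tests
  out
}

#' PCA overfitting check
#'
#' Finds the smallest number of leading principal components of the feature
#' matrix for which the linear SVM reaches 100% in-sample balanced accuracy
#' (averaged over the training folds of one stratified k-fold partition), and
#' reports the held-out balanced accuracy in that reduced space. Comparable
#' full-space and reduced-space held-out accuracies indicate the regularized
#' SVM is not overfitting the p >> n feature space.
#'
#' @inheritParams repeated_cv_bca
#' @return List with `pca_dims`, `pca_bca` (held-out, percent) and `reached`
#'   (FALSE when 100% in-sample accuracy was never attained; `pca_dims` is
#'   then the search cap).
#' @export
pca_overfit_check <- function(X, labels, n_folds = 10, cost = 1, seed = 1) {
  X <- as.matrix(X)
  y_int <- as.integer(factor(labels))
  folds <- withr::with_seed(seed, stratified_folds(y_int, n_folds))
  fold_ids <- unique(folds)
  pcas <- lapply(fold_ids, function(f) prcomp(X[folds != f, , drop = FALSE],
                                              center = TRUE, scale. = FALSE))
  k_max <- min(nrow(X) - 1, ncol(X))
  for (k in seq_len(k_max)) {
    insample <- vapply(seq_along(fold_ids), function(i) {
      f <- fold_ids[i]; tr <- folds != f
      kk <- min(k, ncol(pcas[[i]]$rotation))
      S <- pcas[[i]]$x[, seq_len(kk), drop = FALSE]
      pred <- svm_fit_predict(S, y_int[tr], S, cost)
      bca_codes(y_int[tr], pred)
    }, numeric(1))
    if (mean(insample) >= 100) {
      pred <- integer(length(y_int))
      for (i in seq_along(fold_ids)) {
        f <- fold_ids[i]; tr <- folds != f
        kk <- min(k, ncol(pcas[[i]]$rotation))
        S <- pcas[[i]]$x[, seq_len(kk), drop = FALSE]
        Ste <- scale(X[!tr, , drop = FALSE], center = pcas[[i]]$center,
                     scale = FALSE) %*% pcas[[i]]$rotation[, seq_len(kk), drop = FALSE]
        pred[!tr] <- svm_fit_predict(S, y_int[tr], Ste, cost)
      }
      return(list(pca_dims = k, pca_bca = bca_codes(y_int, pred),
                  reached = TRUE))
    }
  }
  list(pca_dims = k_max, pca_bca = NA_real_, reached = FALSE)
}

#' Compare two sets of balanced accuracies
#'
#' Two-tailed Mann-Whitney U test between two collections of region-level
#' balanced accuracies (e.g. thalamic ROIs inside versus outside the
#' reciprocal striato-thalamic loop). `U` counts pairs where the first set
#' lies below the second, so a first set that is uniformly *higher* yields
#' `U = 0`.
#'
#' @param bcas_a,bcas_b Numeric vectors of balanced accuracies.
#' @return An `mwu_test` object (see [mann_whitney()]).
#' @export
compare_bca_sets <- function(bcas_a, bcas_b) {
  mann_whitney(bcas_a, bcas_b)
}

#' Correlation between regional accuracy and cortical hierarchy rank
#'
#' Spearman correlation between per-ROI balanced accuracies and integer
#' hierarchy ranks (unimodal = high rank, transmodal = low rank) over the
#' shared ROIs, with the two-sided p-value of `stats::cor.test`.
#'
#' @param bcas_by_roi Named numeric vector of balanced accuracies.
#' @param hierarchy_rank Named numeric/integer vector of hierarchy ranks.
#' @return List with `rho`, `p`, `n`.
#' @export
hierarchy_correlation <- function(bcas_by_roi, hierarchy_rank) {
  shared <- intersect(names(bcas_by_roi), names(hierarchy_rank))
  if (length(shared) < 5) stop("need at least 5 shared ROIs", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(bcas_by_roi[shared], hierarchy_rank[shared], method = "spearman")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
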