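# rank statistics for all feature columns at once; column ranks and tie terms
# do not depend on the group labels, so permutation loops only re-sum ranks
make_feature_scorer <- function(X) {
  n <- nrow(X)
  ranks <- apply(X, 2, rank)
  tie_terms <- apply(X, 2, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  }) / (n * (n - 1))
  function(y_int) {
    idx1 <- y_int == 1L
    n1 <- sum(idx1); n2 <- n - n1
    rx <- colSums(ranks[idx1, , drop = FALSE])
    u <- n1 * n2 - (rx - n1 * (n1 + 1) / 2) # pairs group1 < group2
    v <- n1 * n2 / 12 * ((n + 1) - tie_terms)
    z <- (u - n1 * n2 / 2) / sqrt(v)
    z[!is.finite(z)] <- NaN
    z
  }
}

#' Signed rank-sum feature scores for one ROI contrast
#'
#' For every feature, the signed Mann-Whitney rank-sum statistic (the
#' normal-approximation z-value, tie-corrected, no continuity correction)
#' comparing baseline-subtracted feature values between two groups. The sign
#' is positive when the stimulation group (second element of `groups`) takes
#' larger values. P-values are two-sided normal and FDR-corrected across all
#' retained features.
#'
#' @param delta Delta-feature tibble from [delta_features()].
#' @param roi ROI label to score.
#' @param groups Character vector `c(reference, stimulation)`.
#' @return Tibble of class `feature_scores` with columns `feature_id`,
#'   `score`, `p`, `p_fdr`, ordered by decreasing `|score|`. Degenerate
#'   (constant) features are skipped.
#' @export
score_features <- function(delta, roi, groups) {
  stopifnot(length(groups) == 2)
  dm <- delta_matrix(dplyr::filter(delta, .data$group %in% groups), roi,
                     groups = groups)
  keep <- colSums(!is.finite(dm$X)) == 0
  X <- dm$X[, keep, drop = FALSE]
  y_int <- as.integer(factor(as.character(dm$group), levels = groups))
  z <- make_feature_scorer(X)(y_int)
  ok <- is.finite(z)
  out <- tibble::tibble(
    feature_id = colnames(X)[ok],
    score = unname(z[ok]),
    p = unname(2 * pnorm(-abs(z[ok])))
  )
  out$p_fdr <- bh_fdr(out$p)
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$score)))
  class(out) <- c("feature_scores", class(out))
  out
}

#' Select the most discriminative features
#'
#' @param scores A `feature_scores` tibble.
#' @param n Maximum number of features (default 100).
#' @param p_fdr_max FDR threshold (default 0.01).
#' @return Character vector of feature ids ordered by decreasing `|score|`.
#' @export
select_top_features <- function(scores, n = 100, p_fdr_max = 0.01) {
  scores |>
    dplyr::filter(.data$p_fdr < p_fdr_max) |>
    dplyr::arrange(dplyr::desc(abs(.data$score))) |>
    dplyr::slice_head(n = n) |>
    dplyr::pull("feature_id")
}

#' Cluster discriminative features by rank-correlation similarity
#'
#' Pairwise feature dissimilarity is the absolute Spearman correlation
#' distance `1 - |rho|` computed across animals; features are grouped by
#' hierarchical average-linkage clustering and a flat cut at `cut_height`.
#'
#' @param x Either an animals x features numeric matrix, or a delta-feature
#'   tibble (then `roi` and `features` select the matrix).
#' @param roi,features ROI label and feature ids (tibble input only; `features
#'   = NULL` keeps all).
#' @param cut_height Distance at which the dendrogram is cut into flat
#'   clusters (default 0.43).
#' @return Object of class `feature_clusters`: list with `dist` (matrix),
#'   `hclust`, `leaf_order` (feature ids in dendrogram order), `clusters`
#'   (named integer vector), `dropped` (constant features excluded).
#' @export
cluster_top_features <- function(x, roi = NULL, features = NULL,
                                 cut_height = 0.43) {
  if (is.matrix(x)) {
    X <- x
  } else {
    stopifnot(!is.null(roi))
    X <- delta_matrix(x, roi, feature_ids = features)$X
  }
  if (nrow(X) < 4) stop("need at least 4 animals", call. = FALSE)
  const <- apply(X, 2, function(v) !all(is.finite(v)) || var(v) == 0)
  dropped <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 non-constant features", call. = FALSE)
  rho <- suppressWarnings(cor(X, method = "spearman"))
  d <- 1 - abs(rho)
  d[d < 0] <- 0
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  structure(
    list(dist = d, hclust = hc, leaf_order = colnames(X)[hc$order],
         clusters = cutree(hc, h = cut_height), dropped = dropped),
    class = "feature_clusters"
  )
}

#' Write a feature dendrogram as Newick
#'
#' Serializes the average-linkage merge tree of a [cluster_top_features()]
#' result to a plain-text Newick file for external dendrogram tooling.
#'
#' @param fc A `feature_clusters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_tree <- function(fc, path) {
  ape::write.tree(ape::as.phylo(fc$hclust), file = path)
  invisible(path)
}

#' Cross-region correlation of feature scores with correlated shuffles
#'
#' Tests whether two ROIs change their time-series properties in broadly
#' similar ways: the observed statistic is the Spearman correlation between
#' the two ROIs' feature-score vectors; the null applies each group-label
#' shuffle *consistently to both ROIs* (preserving the within-animal
#' dependence between regions) and recomputes both score vectors. The add-one
#' permutation p-value is one-sided for positive correlation by default.
#'
#' @param delta Delta-feature tibble covering both ROIs (same animals).
#' @param roi1,roi2 ROI labels.
#' @param groups Character vector `c(reference, stimulation)`.
#' @param n_perm Number of correlated label shuffles (default 5000).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed Integer seed.
#' @return List with `rho`, `p_perm`, `null_rhos`, `n_features`.
#' @export
cross_region_score_correlation <- function(delta, roi1, roi2, groups,
                                           n_perm = 5000,
                                           alternative = c("greater", "two.sided"),
                                           seed = 1) {
  alternative <- match.arg(alternative)
  d <- dplyr::filter(delta, .data$group %in% groups,
                     .data$roi %in% c(roi1, roi2))
  mask <- well_behaved_mask(d)
  d <- dplyr::filter(d, .data$feature_id %in% mask)
  dm1 <- delta_matrix(d, roi1, groups = groups)
  dm2 <- delta_matrix(d, roi2, groups = groups)
  if (!identical(dm1$animal, dm2$animal)) {
    stop("the two ROIs must cover the same animals", call. = FALSE)
  }
  y_int <- as.integer(factor(as.character(dm1$group), levels = groups))
  s1 <- make_feature_scorer(dm1$X)
  s2 <- make_feature_scorer(dm2$X)
  rho_of <- function(y) {
    z1 <- s1(y); z2 <- s2(y)
    ok <- is.finite(z1) & is.finite(z2)
    spearman_rho(z1[ok], z2[ok])
  }
  rho <- rho_of(y_int)
  null_rhos <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) rho_of(sample(y_int)), numeric(1))
  })
  # round before tail counting so exact ties (e.g. duplicated regions) are not
  # split by floating-point noise in the rank correlation
  rho_r <- round(rho, 12)
  null_r <- round(null_rhos, 12)
  p <- if (alternative == "greater") {
    perm_pvalue(rho_r, null_r)
  } else {
    perm_pvalue(abs(rho_r), abs(null_r))
  }
  list(rho = rho, p_perm = p, null_rhos = null_rhos,
       n_features = sum(is.finite(s1(y_int)) & is.finite(s2(y_int))))
}
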