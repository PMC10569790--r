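#' Two-sample Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, reporting the U statistic,
#' the uncorrected normal-approximation z-value, and both the asymptotic and
#' (when available) the exact two-sided p-value.
#'
#' The statistic is `U = #\{(i, j): x_i < y_j\}` (pairs where the first sample
#' is *below* the second; ties contribute 1/2). The z-value uses the
#' tie-corrected null variance and **no continuity correction**,
#' `z = (U - n1 n2 / 2) / sqrt(Var0(U))`. The exact p-value is twice the
#' smaller tail of the fully enumerated tie-free null distribution of U,
#' capped at 1; it is computed only when the data are tie-free and
#' `n1 + n2 <= exact_limit`. With ties the exact path is refused and the
#' normal approximation is returned with `tie_fallback = TRUE`.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_limit Maximum combined sample size for which the exact null
#'   distribution is enumerated (default 25).
#' @return An object of class `mwu_test`: a list with elements `u_statistic`,
#'   `z_value`, `p_exact` (NA when unavailable), `p_normal`, `n1`, `n2`,
#'   `ties`, `tie_fallback`. Use [tidy()] for a one-row tibble.
#' @examples
#' mann_whitney(c(5, 6, 7), c(1, 2, 3, 4))
#' @export
mann_whitney <- function(x, y, exact_limit = 25) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  combined <- c(x, y)
  r <- rank(combined)
  ties <- anyDuplicated(combined) > 0L
  # pairs with x_i > y_j from the x rank sum; complement gives x_i < y_j
  u_greater <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- n1 * n2 - u_greater

  tie_term <- 0
  if (ties) {
    tt <- table(combined)
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
  }
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    z <- 0
    p_normal <- 1
  } else {
    z <- (u - n1 * n2 / 2) / sqrt(v)
    p_normal <- min(1, 2 * pnorm(-abs(z)))
  }

  p_exact <- NA_real_
  tie_fallback <- FALSE
  if (n <= exact_limit) {
    if (ties) {
      tie_fallback <- TRUE
      warning("ties present; exact p-value unavailable, using normal approximation",
              call. = FALSE)
    } else {
      lower <- pwilcox(u, n1, n2)
      upper <- 1 - pwilcox(u - 1, n1, n2)
      p_exact <- min(1, 2 * min(lower, upper))
    }
  }

  structure(
    list(u_statistic = u, z_value = z, p_exact = p_exact, p_normal = p_normal,
         n1 = n1, n2 = n2, ties = ties, tie_fallback = tie_fallback),
    class = "mwu_test"
  )
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test: U(%d,%d) = %g, z = %.3f\n",
              x$n1, x$n2, x$u_statistic, x$z_value))
  cat(sprintf("  p (normal) = %.4g", x$p_normal))
  if (!is.na(x$p_exact)) cat(sprintf(", p (exact) = %.4g", x$p_exact))
  cat("\n")
  invisible(x)
}

#' Tidy a Mann-Whitney test result
#'
#' @param x An `mwu_test` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, z-value and p-values.
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble::tibble(
    u_statistic = x$u_statistic, z_value = x$z_value,
    p_exact = x$p_exact, p_normal = x$p_normal,
    n1 = x$n1, n2 = x$n2, ties = x$ties
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and clipped at 1, returned in
#' the order of the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Permutation p-value with the add-one convention
#'
#' One-sided Monte-Carlo p-value, `p = (1 + #\{null >= observed\}) / (1 + B)`,
#' where larger statistics are more extreme. The add-one convention counts the
#' observed statistic as one member of the null ensemble, so `p > 0` always.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Numeric vector of null statistics.
#' @return A probability in (0, 1\].
#' @examples
#' perm_pvalue(10, c(1, 2, 3))
#' @export
perm_pvalue <- function(observed, null_values) {
  if (length(null_values) == 0) stop("null_values must be non-empty", call. = FALSE)
  if (length(observed) != 1 || !is.finite(observed)) {
    stop("observed must be a finite scalar", call. = FALSE)
  }
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) when either
#'   input is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' One-sample Wilcoxon signed-rank test against zero median
#'
#' Two-sided p-value for the null hypothesis that the distribution is
#' symmetric about zero. Exact zeros are removed first; the exact null
#' distribution is used for n <= 25 when the absolute values are tie-free,
#' otherwise the normal approximation (without continuity correction).
#'
#' @param x Numeric vector; at least 5 non-zero values required.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("inputs must be finite", call. = FALSE)
  x <- x[x != 0]
  if (length(x) == 0) stop("all values are zero", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 non-zero values", call. = FALSE)
  exact <- length(x) <= 25 && anyDuplicated(abs(x)) == 0L
  suppressWarnings(
    wilcox.test(x, mu = 0, exact = exact, correct = FALSE)$p.value
  )
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) for constant
#'   input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Pearson correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}
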