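test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "b")), 100)
  # constant majority-class prediction: one recall 1, the other 0
  truth <- rep(c("ctrl", "stim"), c(10, 13))
  expect_equal(balanced_accuracy(truth, rep("stim", 23)), 50)
  # sensitivity 1, specificity 0.5
  truth2 <- rep(c("pos", "neg"), c(4, 4))
  pred2 <- c(rep("pos", 4), c("neg", "neg", "pos", "pos"))
  expect_equal(balanced_accuracy(truth2, pred2), 75)
  expect_error(balanced_accuracy(rep("a", 5), rep("a", 5)), "two classes")
})

test_that("lean linear SVM path reproduces e1071::svm predictions exactly", {
  withr::with_seed(17, {
    for (i in 1:40) {
      n1 <- sample(3:10, 1); n2 <- sample(3:12, 1); p <- sample(2:40, 1)
      X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
      y <- factor(rep(c("a", "b"), c(n1, n2)))
      o <- sample(n1 + n2)
      X <- X[o, , drop = FALSE]; y <- y[o]
      y_int <- as.integer(y)
      w <- bolddyn:::inverse_prob_weights(y_int)
      Z <- matrix(rnorm(15 * p), 15, p)
      ref <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE,
                        class.weights = setNames(w, levels(y)))
      expect_identical(levels(y)[bolddyn:::svm_fit_predict(X, y_int, Z)],
                       as.character(predict(ref, Z)))
    }
  })
})

test_that("repeated CV reaches 100 on separable data and is seed-deterministic", {
  sep <- separable_data(n1 = 8, n2 = 10, gap = 6)
  r1 <- repeated_cv_bca(sep$X, sep$y, n_repeats = 5, seed = 3)
  expect_equal(r1$bca_mean, 100)
  noise <- separable_data(n1 = 8, n2 = 10, gap = 0, seed = 4)
  r2 <- repeated_cv_bca(noise$X, noise$y, n_repeats = 5, seed = 9)
  r3 <- repeated_cv_bca(noise$X, noise$y, n_repeats = 5, seed = 9)
  expect_identical(r2$bca_mean, r3$bca_mean)
  expect_equal(length(r2$bca_repeats), 5)
  expect_equal(r2$bca_mean, mean(r2$bca_repeats))
  expect_error(repeated_cv_bca(sep$X, rep("a", 18)), "two classes")
})

test_that("null-feature classification centers on 50% balanced accuracy", {
  # many animals, pure-noise features, random labels
  bcas <- vapply(1:5, function(s) {
    withr::with_seed(22 + s, {
      X <- matrix(rnorm(200 * 10), 200, 10)
      y <- factor(rep(c("a", "b"), each = 100))
    })
    repeated_cv_bca(X, y, n_repeats = 3, seed = s)$bca_mean
  }, numeric(1))
  expect_equal(mean(bcas), 50, tolerance = 3 / 50)
})

test_that("permutation test ranks separable data above every null", {
  sep <- separable_data(n1 = 6, n2 = 7, gap = 6, seed = 6)
  rt <- region_permutation_test(sep$X, sep$y, n_perm = 99, n_repeats = 3,
                                seed = 2)
  expect_equal(rt$p_perm, 1 / 100)
  expect_equal(rt$bca_mean, 100)
  expect_equal(mean(rt$null_bcas), 50, tolerance = 8 / 50)
  g <- glance(rt)
  expect_equal(g$n_perm, 99)
  expect_equal(nrow(tidy(rt)), 3)
})

test_that("PCA overfitting check finds small dimensionality when separable", {
  sep <- separable_data(n1 = 10, n2 = 13, gap = 6, seed = 7)
  full <- repeated_cv_bca(sep$X, sep$y, n_repeats = 5, seed = 8)$bca_mean
  pc <- pca_overfit_check(sep$X, sep$y, seed = 8)
  expect_true(pc$reached)
  expect_lte(pc$pca_dims, 3)
  expect_lt(abs(pc$pca_bca - full), 10)
  # duplicated feature columns leave the dimensionality unchanged
  pc_dup <- pca_overfit_check(cbind(sep$X, sep$X), sep$y, seed = 8)
  expect_equal(pc_dup$pca_dims, pc$pca_dims)
})

test_that("pure-noise labels push the PCA dimensionality toward its cap", {
  noise <- separable_data(n1 = 8, n2 = 8, gap = 0, seed = 9)
  pc <- pca_overfit_check(noise$X, noise$y, seed = 10)
  sep <- separable_data(n1 = 8, n2 = 8, gap = 6, seed = 9)
  pc_sep <- pca_overfit_check(sep$X, sep$y, seed = 10)
  expect_gt(pc$pca_dims, pc_sep$pca_dims)
})

test_that("compare_bca_sets reproduces the loop versus non-loop statistics", {
  loop_bcas <- c(95, 91, 88, 86, 84, 82)      # uniformly above
  nonloop_bcas <- c(71, 68, 66, 63, 61, 58, 55, 52)
  m <- compare_bca_sets(nonloop_bcas, loop_bcas) # U counts first < second
  expect_equal(m$u_statistic, 48)               # complement of 0
  m0 <- compare_bca_sets(loop_bcas, nonloop_bcas)
  expect_equal(m0$u_statistic, 0)
  expect_equal(round(m0$z_value, 2), -3.10)
  expect_equal(signif(m0$p_exact, 1), 7e-4)
})

test_that("hierarchy correlation recovers monotone and null structure", {
  bca <- setNames(50 + (1:12) * 2 + 0.1 * sin(1:12), sprintf("C%02d", 1:12))
  rk <- setNames(1:12, sprintf("C%02d", 1:12))
  h <- hierarchy_correlation(bca, rk)
  expect_equal(h$rho, 1)
  expect_lt(h$p, 0.001)
  expect_error(hierarchy_correlation(bca[1:3], rk), "at least 5")
  withr::with_seed(30, {
    rhos <- replicate(30, hierarchy_correlation(
      setNames(rnorm(12), names(rk)), rk)$rho)
  })
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("classify_regions corrects across ROIs and attaches tests", {
  # affected ROI: every feature shifted between groups (post-normalization
  # separation survives the sigmoid squashing)
  sig <- random_delta_matrix(11, 8, seed = 11) * 0.3 +
    matrix(rep(c(0, 2), c(5, 6)), 11, 8)
  mats <- list(sig = sig, null = random_delta_matrix(11, 8, seed = 12))
  groups <- rep(c("control", "excitation"), c(5, 6))
  delta <- delta_from_matrices(mats, groups)
  cl <- classify_regions(delta, c("control", "excitation"), n_perm = 99,
                         n_repeats = 3, seed = 13)
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$p_fdr >= cl$p_perm))
  expect_gt(cl$bca_mean[cl$roi == "sig"], cl$bca_mean[cl$roi == "null"])
  expect_equal(names(attr(cl, "tests")), c("sig", "null"))
})
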