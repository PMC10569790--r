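# fixtures built in code; all randomness seeded at the call site

make_ar1 <- function(n, phi, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    as.numeric(stats::filter(rnorm(n + 200, 0, sd), phi,
                             method = "recursive"))[-(1:200)]
  })
}

# minimal long-format feature tibble for preprocess tests
toy_features <- function() {
  grid <- tidyr::expand_grid(
    animal = c("a1", "a2", "a3", "a4"),
    roi = "R1",
    period = c("baseline", "post"),
    feature_id = c("f1", "f2", "f3")
  )
  grid$group <- rep(c("g1", "g1", "g2", "g2"), each = 6)
  grid$value <- seq(0.1, by = 0.37, length.out = nrow(grid))
  grid
}

# small, fast synthetic configuration: short session, few animals
tiny_config <- function(n_rois = 3, seed = 1,
                        group_sizes = c(control = 4, excitation = 5),
                        delta_phi = NULL, bandpass = FALSE) {
  rois <- tibble::tibble(
    roi = sprintf("R%d", seq_len(n_rois)),
    category = c("seed", "thalamic-loop",
                 "thalamic-nonloop")[pmin(seq_len(n_rois), 3)],
    rank = NA_integer_
  )
  synth_config(
    group_sizes = group_sizes, rois = rois,
    session_length = 650, injection_index = 256, post_skip = 60,
    period_length = 256, delta_phi = delta_phi, bandpass = bandpass,
    seed = seed
  )
}

# animals x features matrix with a clean two-class linear separation
separable_data <- function(n1 = 10, n2 = 13, p = 20, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
    X[, 1] <- c(rnorm(n1, -gap / 2, 0.3), rnorm(n2, gap / 2, 0.3))
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = factor(rep(c("ctrl", "stim"), c(n1, n2))))
  })
}

# delta-feature tibble assembled directly from per-ROI matrices
delta_from_matrices <- function(mats, groups) {
  purrr::imap_dfr(mats, function(X, roi) {
    tibble::tibble(
      animal = rep(rownames(X), times = ncol(X)),
      group = rep(groups, times = ncol(X)),
      roi = roi,
      feature_id = rep(colnames(X), each = nrow(X)),
      delta = as.numeric(X)
    )
  })
}

random_delta_matrix <- function(n, p, seed, prefix = "f") {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("m%02d", seq_len(n)),
                                sprintf("%s%03d", prefix, seq_len(p))))
    X
  })
}
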