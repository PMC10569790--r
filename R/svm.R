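# Lean interface to the linear two-class C-SVM.
#
# The optimizer is libsvm, reached through e1071's registered `svmtrain`
# routine. e1071::svm()'s R-side preprocessing (data.frame coercion,
# na.action, fitted values) costs ~10x the C solve for the tiny problems the
# permutation loops fit millions of times, so arguments are marshalled here
# once and the linear decision function w'x - rho is evaluated directly.
# Agreement with e1071::svm() predictions is enforced in the test suite.

svmtrain_symbol <- function() {
  if (is.null(.bolddyn_env$svmtrain)) {
    loadNamespace("e1071") # ensures the shared library is loaded
    .bolddyn_env$svmtrain <-
      getNativeSymbolInfo("svmtrain", PACKAGE = "e1071")$address
  }
  .bolddyn_env$svmtrain
}

# X: numeric matrix; y_int: integer class codes (1, 2); weights: length-2
# numeric, weights[c] for class code c. Returns linear decision rule.
linear_svm_train <- function(X, y_int, weights, cost = 1) {
  nr <- nrow(X)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(svmtrain_symbol(),
    as.double(t(X)), as.integer(nr), as.integer(ncol(X)), as.double(y_int),
    as.integer(0), as.integer(0),
    as.integer(0),           # type: C-classification
    as.integer(0),           # kernel: linear
    as.integer(3), as.double(0), as.double(0),
    as.double(cost), as.double(0.5),
    as.integer(1:2), as.double(weights), as.integer(2L),
    as.double(40), as.double(0.001), as.double(0.1),
    as.integer(1), as.integer(0), as.integer(0), as.integer(0),
    nclasses = integer(1), nr = integer(1), index = integer(nr),
    labels = integer(2), nSV = integer(2), rho = double(1),
    coefs = double(nr), sigma = double(1), probA = double(1),
    probB = double(1), cresults = double(0), ctotal1 = double(1),
    ctotal2 = double(1), error = err)
  if (cret$error != err) stop(cret$error, call. = FALSE)
  idx <- cret$index[seq_len(cret$nr)]
  list(
    w = drop(crossprod(X[idx, , drop = FALSE], cret$coefs[seq_len(cret$nr)])),
    rho = cret$rho,
    lab_pos = cret$labels[1], lab_neg = cret$labels[2]
  )
}

linear_svm_predict <- function(fit, X) {
  d <- drop(X %*% fit$w) - fit$rho
  ifelse(d > 0, fit$lab_pos, fit$lab_neg)
}

# inverse-probability class weights N / (2 n_c) for codes 1, 2
inverse_prob_weights <- function(y_int) {
  n1 <- sum(y_int == 1L); n2 <- sum(y_int == 2L)
  n <- n1 + n2
  c(n / (2 * n1), n / (2 * n2))
}

# train on (Xtr, ytr codes), predict codes for Xte
svm_fit_predict <- function(Xtr, ytr_int, Xte, cost = 1) {
  fit <- linear_svm_train(Xtr, ytr_int, inverse_prob_weights(ytr_int), cost)
  linear_svm_predict(fit, Xte)
}
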