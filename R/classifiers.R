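#' Fit a kernel extreme learning machine
#'
#' Kernelized ELM with the RBF kernel
#' `k(x, y) = exp(-gamma * ||x - y||^2)`. The output weights `beta` solve
#' the ridge-regularized kernel system
#' `(K + I / C_reg) beta = T` where `K` is the training Gram matrix and
#' `T` the one-hot class-indicator matrix; decision scores for a query are
#' its kernel row against the training set times `beta`. With `C_reg > 0`
#' the system is symmetric positive definite, so the solve cannot be
#' singular.
#'
#' @param x Numeric training matrix (n x D).
#' @param y Class labels, length n; every represented class needs at least
#'   one sample.
#' @param gamma RBF kernel width (> 0). The default 0.005 is the
#'   conventional setting for the 128-dim gas-sensor drift features.
#' @param C_reg Ridge regularization constant (> 0); larger values fit the
#'   training data more tightly.
#' @return An object of class `kelm` usable with [predict_proba()] and
#'   `predict()`.
#' @examples
#' m <- fit_kernel_elm(matrix(c(-5, 5)), c("a", "b"))
#' predict_proba(m, matrix(0))  # equidistant query -> (0.5, 0.5)
#' @export
fit_kernel_elm <- function(x, y, gamma = 0.005, C_reg = 100) {
  x <- as.matrix(x)
  if (!(gamma > 0)) stop("gamma must be positive")
  if (!(C_reg > 0)) stop("C_reg must be positive")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  Tmat <- matrix(0, nrow(x), length(classes))
  Tmat[cbind(seq_len(nrow(x)), yi)] <- 1
  K <- rbf_kernel(x, x, gamma)
  beta <- solve(K + diag(1 / C_reg, nrow(x)), Tmat)
  structure(list(x = x, beta = beta, classes = classes,
                 gamma = gamma, C_reg = C_reg),
            class = "kelm")
}

rbf_kernel <- function(a, b, gamma) {
  # squared Euclidean distances via the expansion ||a||^2 + ||b||^2 - 2ab'
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Per-class posterior probabilities of a fitted learner
#'
#' Generic contract every learner in the package honors: given query
#' instances, return a matrix of per-class posteriors, each row a
#' probability simplex (non-negative, summing to 1). Raw decision scores
#' are mapped to the simplex by a softmax.
#'
#' @param learner A fitted learner (`kelm` or `lsvm`).
#' @param x Query matrix (rows are instances) or a single feature vector.
#' @return Numeric matrix, one row per query, columns named by class.
#' @export
predict_proba <- function(learner, x) UseMethod("predict_proba")

#' @export
predict_proba.kelm <- function(learner, x) {
  x <- query_matrix(x, ncol(learner$x))
  scores <- rbf_kernel(x, learner$x, learner$gamma) %*% learner$beta
  softmax_rows(scores, learner$classes)
}

#' @export
predict_proba.default <- function(learner, x) {
  stop("predict_proba: unfitted or unsupported learner of class ",
       paste(class(learner), collapse = "/"))
}

#' Predicted class labels
#' @param object A fitted learner.
#' @param newdata Query matrix.
#' @param ... Unused.
#' @return Character vector of predicted classes (ties to the
#'   first class in sorted order).
#' @export
predict.kelm <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  colnames(p)[max.col(p, ties.method = "first")]
}

softmax_rows <- function(scores, classes) {
  z <- scores - apply(scores, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  colnames(p) <- classes
  p
}

query_matrix <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != d) stop(sprintf("query dimension %d != training dimension %d",
                                 ncol(x), d))
  x
}

#' Fit a linear support vector machine learner
#'
#' Thin wrapper around [e1071::svm()] (linear kernel) exposing the same
#' probabilistic contract as the kernel ELM: posteriors are a softmax over
#' the per-class one-vs-one decision-value votes, keeping the calibration
#' convention uniform across learners.
#'
#' @param x Training matrix.
#' @param y Class labels.
#' @param cost Soft-margin penalty `C` (default 0.2, the conventional
#'   linear-SVM setting for the drift features).
#' @return An object of class `lsvm`.
#' @export
fit_linear_svm <- function(x, y, cost = 0.2) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(y)))
  fit <- e1071::svm(x, factor(as.character(y), levels = classes),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(fit = fit, classes = classes), class = "lsvm")
}

#' @export
predict_proba.lsvm <- function(learner, x) {
  x <- query_matrix(x, ncol(learner$fit$SV))
  dv <- attr(stats::predict(learner$fit, x, decision.values = TRUE),
             "decision.values")
  K <- length(learner$classes)
  scores <- matrix(0, nrow(x), K, dimnames = list(NULL, learner$classes))
  if (K == 1L) return(softmax_rows(scores, learner$classes))
  # accumulate signed one-vs-one decision values per class
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
  }
  softmax_rows(scores / max(1, K - 1), learner$classes)
}

#' @export
predict.lsvm <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  colnames(p)[max.col(p, ties.method = "first")]
}

#' Fit the configured learner type
#'
#' @param x,y Training data.
#' @param classifier List with `type` ("kelm" or "lsvm") and
#'   hyperparameters (`gamma`, `C_reg` for kelm; `cost` for lsvm).
#' @return A fitted learner.
#' @export
fit_learner <- function(x, y, classifier = list(type = "kelm")) {
  type <- classifier$type %||% "kelm"
  switch(type,
         kelm = fit_kernel_elm(x, y,
                               gamma = classifier$gamma %||% 0.005,
                               C_reg = classifier$C_reg %||% 100),
         lsvm = fit_linear_svm(x, y, cost = classifier$cost %||% 0.2),
         stop("unknown classifier type: ", type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a chair-plus-members committee
#'
#' The chair is fitted on the full labeled set and performs recognition;
#' each member is fitted on a stratified bootstrap resample (same size,
#' with replacement, drawn within class) and is used only to measure
#' disagreement. A resample missing a class is redrawn (bounded retries),
#' then one exemplar of the missing class is forced in.
#'
#' @param x,y Labeled training data.
#' @param k_members Number of members (>= 2; default 2).
#' @param seed Integer seed controlling the resamples.
#' @param classifier Learner configuration as in [fit_learner()].
#' @return An object of class `al_committee`: list with `chair` and
#'   `members`.
#' @export
build_committee <- function(x, y, k_members = 2L, seed = 1L,
                            classifier = list(type = "kelm")) {
  if (k_members < 2L) stop("a committee needs at least 2 members")
  x <- as.matrix(x); y <- as.character(y)
  chair <- fit_learner(x, y, classifier)
  members <- vector("list", k_members)
  for (m in seq_len(k_members)) {
    set.seed(derive_seed(seed, "member", m))
    idx <- stratified_bootstrap(y)
    members[[m]] <- fit_learner(x[idx, , drop = FALSE], y[idx], classifier)
  }
  structure(list(chair = chair, members = members), class = "al_committee")
}

stratified_bootstrap <- function(y, max_retry = 10L) {
  classes <- unique(y)
  for (r in seq_len(max_retry)) {
    idx <- unlist(lapply(classes, function(cl) {
      members <- which(y == cl)
      if (length(members) == 1L) members
      else sample(members, length(members), replace = TRUE)
    }))
    if (setequal(unique(y[idx]), classes)) return(sort(idx))
  }
  # force one exemplar of each missing class (unreachable with the
  # within-class draw above, kept as a guard)
  missing <- setdiff(classes, unique(y[idx]))
  sort(c(idx, vapply(missing, function(cl) which(y == cl)[1], 1L)))
}
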