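#' Posterior margin of a single instance
#'
#' Difference between the largest and second-largest posterior
#' probability. A small margin means the learner is torn between two
#' classes, i.e. high uncertainty; uncertainty sampling selects the
#' pool instance with the minimum margin.
#'
#' @param posterior Probability simplex vector over K >= 2 classes.
#' @return Margin in `[0, 1]`.
#' @examples
#' margin_score(c(0.6, 0.3, 0.1))  # 0.3
#' @export
margin_score <- function(posterior) {
  check_simplex(posterior, min_k = 2L)
  s <- sort(posterior, decreasing = TRUE)
  s[1] - s[2]
}

#' Committee disagreement as mean Kullback-Leibler divergence
#'
#' Query-by-committee measures an instance's value as the disagreement of
#' the committee members' posteriors: the average, over members, of the
#' KL divergence from a member's posterior to the consensus (the
#' arithmetic mean of all member posteriors). Natural logarithm;
#' `0 * log(0 / q)` is taken as 0.
#'
#' @param member_posteriors Matrix with one member posterior per row (or a
#'   list of simplex vectors), all over the same label set.
#' @return Non-negative scalar, 0 iff all members agree exactly.
#' @examples
#' kld_score(rbind(c(1, 0), c(0, 1)))  # log(2)
#' @export
kld_score <- function(member_posteriors) {
  P <- as_posterior_matrix(member_posteriors)
  if (nrow(P) < 2L) stop("a committee needs at least 2 members")
  consensus <- colMeans(P)
  kl <- apply(P, 1, function(p) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / consensus[nz]))
  })
  mean(kl)
}

#' Expected generalization loss of a learner over the data pool
#'
#' Two standard loss estimates over the (renewed) data pool: the
#' logarithmic loss, i.e. the mean Shannon entropy of the pool posteriors
#' (natural log), or the 0/1 loss, i.e. the mean of one minus the maximum
#' posterior.
#'
#' @param pool_posteriors Matrix of pool posteriors (rows = instances) or
#'   a list of simplex vectors.
#' @param loss `"log"` (default) or `"zero_one"`.
#' @return Non-negative scalar; 0 when every posterior is one-hot.
#' @export
er_pool_loss <- function(pool_posteriors, loss = c("log", "zero_one")) {
  loss <- match.arg(loss)
  P <- as_posterior_matrix(pool_posteriors)
  if (nrow(P) == 0L) stop("empty pool")
  if (loss == "log") {
    ent <- apply(P, 1, function(p) { nz <- p > 0; -sum(p[nz] * log(p[nz])) })
    mean(ent)
  } else {
    mean(1 - apply(P, 1, max))
  }
}

#' Expected-error-reduction score of one pool candidate
#'
#' Values a candidate by how much labeling it is expected to reduce the
#' learner's loss over the rest of the pool: for every hypothetical label
#' `y`, the learner is retrained on the training set plus the candidate
#' labeled `y`, the pool loss (excluding the candidate) is recomputed, and
#' the hypothetical losses are averaged with the current posterior
#' `P(y | candidate)` as weights. The score is the current pool loss minus
#' this expectation, clamped below at a small `eps > 0` so scores stay
#' strictly positive. With a pool larger than `pool_cap`, losses are
#' evaluated on a seeded subsample of the pool for tractability
#' (`pool_cap = Inf` gives the exact score).
#'
#' @param cand_idx Row index of the candidate within `pool_x`.
#' @param learner Current fitted learner.
#' @param train_x,train_y Current labeled training data.
#' @param pool_x Pool feature matrix.
#' @param loss Loss passed to [er_pool_loss()].
#' @param pool_cap Max pool rows used in the loss evaluation (default
#'   200).
#' @param seed Seed for the subsample.
#' @param classifier Learner configuration for the retrains.
#' @param eps Positivity clamp (default 1e-12).
#' @return Positive scalar score (larger = more expected loss reduction).
#' @export
er_score <- function(cand_idx, learner, train_x, train_y, pool_x,
                     loss = "log", pool_cap = 200L, seed = 1L,
                     classifier = list(type = "kelm"), eps = 1e-12) {
  n_pool <- nrow(pool_x)
  eval_idx <- setdiff(seq_len(n_pool), cand_idx)
  if (length(eval_idx) > pool_cap) {
    set.seed(derive_seed(seed, "er_subsample"))
    eval_idx <- sort(sample(eval_idx, pool_cap))
  }
  if (length(eval_idx) == 0L) return(eps)  # singleton pool: remainder loss 0
  eval_x <- pool_x[eval_idx, , drop = FALSE]
  current <- er_pool_loss(predict_proba(learner, eval_x), loss)
  post <- predict_proba(learner, pool_x[cand_idx, , drop = FALSE])[1, ]
  expected <- 0
  for (cl in names(post)) {
    if (post[[cl]] == 0) next
    refit <- fit_learner(rbind(train_x, pool_x[cand_idx, , drop = FALSE]),
                         c(train_y, cl), classifier)
    expected <- expected + post[[cl] ] *
      er_pool_loss(predict_proba(refit, eval_x), loss)
  }
  max(current - expected, eps)
}

check_simplex <- function(p, min_k = 1L, tol = 1e-9) {
  if (length(p) < min_k) stop("posterior needs at least ", min_k, " classes")
  if (any(p < -tol) || abs(sum(p) - 1) > tol)
    stop("not a probability simplex (non-negative, summing to 1)")
  invisible(p)
}

as_posterior_matrix <- function(p) {
  if (is.list(p)) p <- do.call(rbind, p)
  p <- as.matrix(p)
  if (nrow(p) > 0) apply(p, 1, check_simplex)
  p
}
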