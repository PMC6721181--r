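#' Per-class mean vectors of a training set
#'
#' Seeds for the dynamic clustering: the mean feature vector of each class
#' in the current training set. Every class of `classes` must be
#' represented.
#'
#' @param x Training matrix.
#' @param y Class labels.
#' @param classes Full ordered label set (default: sorted unique labels).
#' @return Matrix with one row per class (rownames = classes).
#' @export
init_class_means <- function(x, y, classes = sort(unique(as.character(y)))) {
  y <- as.character(y)
  missing <- setdiff(classes, unique(y))
  if (length(missing))
    stop("training set has no sample of class: ", paste(missing, collapse = ", "))
  m <- t(vapply(classes,
                function(cl) colMeans(x[y == cl, , drop = FALSE]),
                numeric(ncol(x))))
  rownames(m) <- classes
  m
}

#' Cluster the data pool around class-mean seeds
#'
#' Lloyd-style alternation: assign every pool instance to its nearest
#' (Euclidean) mean, ties to the lowest cluster index, then move each mean
#' to the centroid of its members, iterating until the largest mean
#' displacement falls below `tol` or `max_iter` is reached. The cluster
#' count equals the class count by construction (one seed per class), so
#' clusters track class regions even though the pool is unlabeled. An
#' empty cluster keeps its previous mean.
#'
#' @param pool_x Pool feature matrix (non-empty).
#' @param seed_means K x D matrix of initial means (K >= 2), typically
#'   [init_class_means()] of the current training set.
#' @param tol Convergence tolerance on the max mean displacement.
#' @param max_iter Iteration cap.
#' @return A list of class `cluster_state`: `means` (K x D),
#'   `assignment` (cluster index per pool row), `counts` (per-cluster
#'   sizes), `iterations`, `wss_trace` (within-cluster sum of squares
#'   after each assignment step, non-increasing).
#' @export
cluster_pool <- function(pool_x, seed_means, tol = 1e-6, max_iter = 100L) {
  pool_x <- as.matrix(pool_x)
  means <- as.matrix(seed_means)
  K <- nrow(means)
  if (K < 2L) stop("need at least 2 clusters")
  if (nrow(pool_x) == 0L) stop("empty pool")
  wss_trace <- numeric(0)
  assignment <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(pool_x, means)
    assignment <- max.col(-d2, ties.method = "first")
    wss_trace <- c(wss_trace, sum(d2[cbind(seq_len(nrow(pool_x)), assignment)]))
    new_means <- means
    for (k in seq_len(K)) {
      members <- assignment == k
      if (any(members))
        new_means[k, ] <- colMeans(pool_x[members, , drop = FALSE])
    }
    shift <- max(sqrt(rowSums((new_means - means)^2)))
    means <- new_means
    if (shift < tol) break
  }
  structure(list(means = means, assignment = assignment,
                 counts = tabulate(assignment, nbins = K),
                 iterations = it, wss_trace = wss_trace),
            class = "cluster_state")
}

sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Select the most valuable eligible cluster
#'
#' Ranks clusters by the mean uncertainty of their members, masked by the
#' binary flag vector: a cluster with flag 0 (recently selected) or no
#' members is ineligible. Ties go to the lowest cluster index.
#'
#' @param state A `cluster_state` from [cluster_pool()].
#' @param scores Positive uncertainty value per pool instance (same order
#'   as the pool rows).
#' @param flags Binary vector, one flag per cluster.
#' @return The selected cluster index `k*`.
#' @export
select_cluster <- function(state, scores, flags) {
  K <- length(state$counts)
  stopifnot(length(flags) == K, length(scores) == length(state$assignment))
  if (all(flags == 0)) stop("all cluster flags are 0; reset flags first")
  value <- rep(-Inf, K)
  for (k in seq_len(K)) {
    if (flags[k] == 1 && state$counts[k] > 0)
      value[k] <- mean(scores[state$assignment == k])
  }
  if (all(value == -Inf)) stop("no eligible non-empty cluster")
  which.max(value)
}

#' Select the most uncertain instance within a cluster
#'
#' @param state A `cluster_state`.
#' @param k Cluster index (non-empty).
#' @param scores Uncertainty value per pool instance.
#' @return Pool row index of the selected instance (ties to the lowest
#'   index).
#' @export
select_instance_in_cluster <- function(state, k, scores) {
  members <- which(state$assignment == k)
  if (!length(members)) stop("cluster ", k, " is empty")
  members[which.max(scores[members])]
}

#' Update the cluster flag vector after a selection
#'
#' Clears the selected cluster's flag so consecutive selections visit
#' different clusters; once every flag is 0 the vector resets to all 1,
#' starting a new alternation cycle.
#'
#' @param flags Binary flag vector.
#' @param k Cluster just selected (its flag must be 1).
#' @return Updated flag vector.
#' @export
update_flags <- function(flags, k) {
  if (flags[k] != 1) stop("cluster ", k, " has flag 0 and cannot be selected")
  flags[k] <- 0
  if (all(flags == 0)) flags[] <- 1
  flags
}

# ---- pool scoring ---------------------------------------------------------

pool_margins <- function(P) {
  apply(P, 1, function(p) { s <- sort(p, decreasing = TRUE); s[1] - s[2] })
}

pool_klds <- function(members, pool_x) {
  Ps <- lapply(members, predict_proba, x = pool_x)
  consensus <- Reduce(`+`, Ps) / length(Ps)
  kl <- lapply(Ps, function(P) {
    term <- P * log(P / consensus)
    term[P == 0] <- 0
    rowSums(term)
  })
  out <- Reduce(`+`, kl) / length(kl)
  # disagreement below the positivity floor is round-off from identical
  # members: snap to an exact 0 so argmax ties resolve by index
  out[out < 1e-12] <- 0
  out
}

#' Uncertainty values of every pool instance under a strategy
#'
#' Maps each strategy's valuation onto a strictly positive scale:
#' uncertainty sampling uses `1 - margin + eps`, query-by-committee the
#' committee KL disagreement plus `eps`, and error-reduction the expected
#' loss reduction (already clamped positive).
#'
#' @param strategy `"us"`, `"qbc"` or `"er"`.
#' @param pool_x Pool feature matrix.
#' @param learner Fitted learner (chair for committee strategies).
#' @param committee `al_committee` (required for `"qbc"`).
#' @param train_x,train_y Current training data (required for `"er"`).
#' @param metric List of ER options: `loss`, `pool_cap`, `seed`.
#' @param classifier Learner configuration for ER retrains.
#' @param eps Positivity offset.
#' @return Positive numeric vector, one value per pool row.
#' @export
pool_uncertainty <- function(strategy, pool_x, learner = NULL,
                             committee = NULL, train_x = NULL, train_y = NULL,
                             metric = list(), classifier = list(type = "kelm"),
                             eps = 1e-12) {
  switch(strategy,
    us = {
      P <- predict_proba(learner, pool_x)
      1 - pool_margins(P) + eps
    },
    qbc = {
      if (is.null(committee)) stop("qbc scoring needs a committee")
      pool_klds(committee$members, pool_x) + eps
    },
    er = {
      vapply(seq_len(nrow(pool_x)), function(i)
        er_score(i, learner, train_x, train_y, pool_x,
                 loss = metric$loss %||% "log",
                 pool_cap = metric$pool_cap %||% 200L,
                 seed = metric$seed %||% 1L,
                 classifier = classifier, eps = eps),
        numeric(1))
    },
    stop("unknown uncertainty strategy: ", strategy))
}

# ---- shared run state -----------------------------------------------------

al_state <- function(train_x, train_y, pool, oracle, classes) {
  list(train_x = as.matrix(train_x), train_y = as.character(train_y),
       pool_x = pool$x, pool_ids = rownames(pool$x),
       oracle = oracle, classes = classes)
}

al_move <- function(st, i) {
  label <- st$oracle(st$pool_ids[i])
  st$train_x <- rbind(st$train_x, st$pool_x[i, , drop = FALSE])
  st$train_y <- c(st$train_y, label)
  st$pool_x <- st$pool_x[-i, , drop = FALSE]
  st$pool_ids <- st$pool_ids[-i]
  st$last_label <- label
  st
}

empty_trace <- function() {
  data.frame(step = integer(0), id = character(0), cluster = integer(0),
             uncertainty = numeric(0), label = character(0),
             acc_before = numeric(0), acc_after = numeric(0),
             stringsAsFactors = FALSE)
}

trace_row <- function(step, id, cluster, unc, label, acc_before, acc_after) {
  data.frame(step = step, id = id,
             cluster = if (is.null(cluster)) NA_integer_ else cluster,
             uncertainty = unc, label = label,
             acc_before = acc_before %||% NA_real_,
             acc_after = acc_after %||% NA_real_,
             stringsAsFactors = FALSE)
}

# ---- runners --------------------------------------------------------------

#' Run the dynamic-clustering active-learning loop
#'
#' Each of the `n_select` iterations (i) recomputes the per-class means of
#' the current training set, (ii) clusters the pool around them with
#' [cluster_pool()], (iii) scores every pool instance with the chosen
#' uncertainty strategy, (iv) selects the most valuable flagged cluster
#' and the most uncertain instance inside it, (v) clears that cluster's
#' flag (resetting the flag vector when it empties), (vi) queries the
#' oracle for the label, moves the instance into the training set, and
#' (vii) refits the learner from scratch. Cluster flags persist across
#' iterations, which forces the selections to alternate over clusters and
#' thereby balances the class composition of the queried labels.
#'
#' @param train_x,train_y Initial labeled training data covering every
#'   class.
#' @param pool A `drift_batch` acting as the unlabeled pool.
#' @param oracle Label oracle, e.g. [make_oracle()].
#' @param n_select Number of instances to query (<= pool size).
#' @param strategy Uncertainty strategy: `"us"`, `"qbc"` or `"er"`.
#' @param classifier Learner configuration (see [fit_learner()]).
#' @param metric ER options (see [pool_uncertainty()]).
#' @param seed Master seed for committee resamples / ER subsampling.
#' @param tol,max_iter Clustering controls.
#' @param recluster Recluster the pool every iteration (default TRUE, the
#'   reference behavior); FALSE freezes the initial clustering.
#' @param eval_fn Optional `function(learner) -> accuracy`, evaluated
#'   before and after each retrain and recorded in the trace.
#' @param classes Full ordered label set.
#' @return A list of class `al_run`: `learner` (final), `trace`
#'   (data.frame: step, id, cluster, uncertainty, label, acc_before,
#'   acc_after), `train_x`, `train_y`, `pool_x`, `pool_ids`, `flags`.
#' @export
run_aldc <- function(train_x, train_y, pool, oracle, n_select,
                     strategy = c("us", "qbc", "er"),
                     classifier = list(type = "kelm"), metric = list(),
                     seed = 1L, tol = 1e-6, max_iter = 100L,
                     recluster = TRUE, eval_fn = NULL,
                     classes = sort(unique(as.character(train_y)))) {
  strategy <- match.arg(strategy)
  st <- al_state(train_x, train_y, pool, oracle, classes)
  if (n_select > length(st$pool_ids)) stop("n_select exceeds the pool size")
  learner <- fit_learner(st$train_x, st$train_y, classifier)
  committee <- if (strategy == "qbc")
    build_committee(st$train_x, st$train_y, seed = derive_seed(seed, "cmt", 0),
                    classifier = classifier)
  flags <- rep(1L, length(classes))
  trace <- empty_trace()
  frozen <- NULL
  for (step in seq_len(n_select)) {
    means <- init_class_means(st$train_x, st$train_y, classes)
    cs <- if (recluster || is.null(frozen)) {
      frozen <- cluster_pool(st$pool_x, means, tol = tol, max_iter = max_iter)
      frozen
    } else {
      # frozen mode: keep cluster membership, drop removed instances
      frozen
    }
    m <- metric
    if (is.null(m$seed)) m$seed <- derive_seed(seed, "er", step)
    scores <- pool_uncertainty(strategy, st$pool_x, learner = learner,
                               committee = committee,
                               train_x = st$train_x, train_y = st$train_y,
                               metric = m, classifier = classifier)
    if (!any(flags == 1 & cs$counts > 0)) flags[] <- 1L
    k_star <- select_cluster(cs, scores, flags)
    i_star <- select_instance_in_cluster(cs, k_star, scores)
    flags <- update_flags(flags, k_star)
    acc_before <- if (!is.null(eval_fn)) eval_fn(learner) else NA_real_
    picked_id <- st$pool_ids[i_star]
    picked_score <- scores[i_star]
    st <- al_move(st, i_star)
    if (!recluster) frozen <- drop_from_state(frozen, i_star)
    learner <- fit_learner(st$train_x, st$train_y, classifier)
    if (strategy == "qbc")
      committee <- build_committee(st$train_x, st$train_y,
                                   seed = derive_seed(seed, "cmt", step),
                                   classifier = classifier)
    acc_after <- if (!is.null(eval_fn)) eval_fn(learner) else NA_real_
    trace <- rbind(trace, trace_row(step, picked_id, k_star, picked_score,
                                    st$last_label, acc_before, acc_after))
  }
  structure(list(learner = learner, trace = trace, train_x = st$train_x,
                 train_y = st$train_y, pool_x = st$pool_x,
                 pool_ids = st$pool_ids, flags = flags),
            class = "al_run")
}

drop_from_state <- function(cs, i) {
  cs$assignment <- cs$assignment[-i]
  cs$counts <- tabulate(cs$assignment, nbins = length(cs$counts))
  cs
}

#' Run a classical pool-based selector (US, QBC or ER)
#'
#' Per iteration the whole pool is scored and the globally most valuable
#' instance is taken: minimum margin for uncertainty sampling, maximum
#' committee KL disagreement for query-by-committee, maximum expected
#' loss reduction for error-reduction sampling. Ties go to the lowest
#' pool index. The learner is refit from scratch after every query.
#'
#' @inheritParams run_aldc
#' @return An `al_run` list (the `cluster` trace column is `NA`).
#' @export
run_baseline <- function(train_x, train_y, pool, oracle, n_select,
                         strategy = c("us", "qbc", "er"),
                         classifier = list(type = "kelm"), metric = list(),
                         seed = 1L, eval_fn = NULL,
                         classes = sort(unique(as.character(train_y)))) {
  strategy <- match.arg(strategy)
  st <- al_state(train_x, train_y, pool, oracle, classes)
  if (n_select > length(st$pool_ids)) stop("n_select exceeds the pool size")
  learner <- fit_learner(st$train_x, st$train_y, classifier)
  committee <- if (strategy == "qbc")
    build_committee(st$train_x, st$train_y, seed = derive_seed(seed, "cmt", 0),
                    classifier = classifier)
  trace <- empty_trace()
  for (step in seq_len(n_select)) {
    m <- metric
    if (is.null(m$seed)) m$seed <- derive_seed(seed, "er", step)
    scores <- pool_uncertainty(strategy, st$pool_x, learner = learner,
                               committee = committee,
                               train_x = st$train_x, train_y = st$train_y,
                               metric = m, classifier = classifier)
    i_star <- which.max(scores)
    acc_before <- if (!is.null(eval_fn)) eval_fn(learner) else NA_real_
    picked_id <- st$pool_ids[i_star]
    picked_score <- scores[i_star]
    st <- al_move(st, i_star)
    learner <- fit_learner(st$train_x, st$train_y, classifier)
    if (strategy == "qbc")
      committee <- build_committee(st$train_x, st$train_y,
                                   seed = derive_seed(seed, "cmt", step),
                                   classifier = classifier)
    acc_after <- if (!is.null(eval_fn)) eval_fn(learner) else NA_real_
    trace <- rbind(trace, trace_row(step, picked_id, NA_integer_, picked_score,
                                    st$last_label, acc_before, acc_after))
  }
  structure(list(learner = learner, trace = trace, train_x = st$train_x,
                 train_y = st$train_y, pool_x = st$pool_x,
                 pool_ids = st$pool_ids),
            class = "al_run")
}

#' Run the adaptive confidence rule selector
#'
#' Committee-based selection that alternates between boundary and
#' class-center instances: each step picks the pool instance with the
#' largest committee KL disagreement if the chair's predicted labels on
#' the pool changed in the previous update (the decision boundary is
#' still moving), and the smallest otherwise (harvest representative
#' center instances). The first step, having no previous update, takes
#' the largest-disagreement branch.
#'
#' @inheritParams run_aldc
#' @return An `al_run` list; `learner` is the final chair. The trace's
#'   `cluster` column is `NA`; its `uncertainty` column holds the KL
#'   disagreement of the picked instance.
#' @export
run_acr <- function(train_x, train_y, pool, oracle, n_select,
                    classifier = list(type = "kelm"), seed = 1L,
                    eval_fn = NULL,
                    classes = sort(unique(as.character(train_y))),
                    metric = list()) {
  st <- al_state(train_x, train_y, pool, oracle, classes)
  if (n_select > length(st$pool_ids)) stop("n_select exceeds the pool size")
  committee <- build_committee(st$train_x, st$train_y,
                               seed = derive_seed(seed, "cmt", 0),
                               classifier = classifier)
  changed <- NA  # no previous update yet
  trace <- empty_trace()
  for (step in seq_len(n_select)) {
    klds <- pool_klds(committee$members, st$pool_x)
    i_star <- if (isFALSE(changed)) which.min(klds) else which.max(klds)
    acc_before <- if (!is.null(eval_fn)) eval_fn(committee$chair) else NA_real_
    picked_id <- st$pool_ids[i_star]
    picked_score <- klds[i_star]
    old_chair <- committee$chair
    st <- al_move(st, i_star)
    committee <- build_committee(st$train_x, st$train_y,
                                 seed = derive_seed(seed, "cmt", step),
                                 classifier = classifier)
    if (nrow(st$pool_x) > 0) {
      before <- predict(old_chair, st$pool_x)
      after <- predict(committee$chair, st$pool_x)
      changed <- any(before != after)
    } else changed <- NA
    acc_after <- if (!is.null(eval_fn)) eval_fn(committee$chair) else NA_real_
    trace <- rbind(trace, trace_row(step, picked_id, NA_integer_, picked_score,
                                    st$last_label, acc_before, acc_after))
  }
  structure(list(learner = committee$chair, trace = trace,
                 train_x = st$train_x, train_y = st$train_y,
                 pool_x = st$pool_x, pool_ids = st$pool_ids),
            class = "al_run")
}

#' Run the random-selection control
#'
#' Queries `n_select` uniformly random pool instances (seeded). Because
#' the final learner does not depend on the order of a random draw, the
#' learner is refit once at the end unless per-step evaluation is
#' requested.
#'
#' @inheritParams run_aldc
#' @return An `al_run` list.
#' @export
run_random <- function(train_x, train_y, pool, oracle, n_select,
                       classifier = list(type = "kelm"), seed = 1L,
                       eval_fn = NULL,
                       classes = sort(unique(as.character(train_y))),
                       metric = list()) {
  st <- al_state(train_x, train_y, pool, oracle, classes)
  if (n_select > length(st$pool_ids)) stop("n_select exceeds the pool size")
  set.seed(derive_seed(seed, "random_pick"))
  order_pick <- sample.int(length(st$pool_ids), n_select)
  trace <- empty_trace()
  learner <- NULL
  if (!is.null(eval_fn))
    learner <- fit_learner(st$train_x, st$train_y, classifier)
  for (step in seq_len(n_select)) {
    # indices shift as instances leave the pool: map ids, not positions
    picked_id <- rownames(pool$x)[order_pick[step]]
    i_star <- match(picked_id, st$pool_ids)
    acc_before <- if (!is.null(eval_fn)) eval_fn(learner) else NA_real_
    st <- al_move(st, i_star)
    if (!is.null(eval_fn)) {
      learner <- fit_learner(st$train_x, st$train_y, classifier)
      acc_after <- eval_fn(learner)
    } else acc_after <- NA_real_
    trace <- rbind(trace, trace_row(step, picked_id, NA_integer_, NA_real_,
                                    st$last_label, acc_before, acc_after))
  }
  if (is.null(learner)) learner <- fit_learner(st$train_x, st$train_y, classifier)
  structure(list(learner = learner, trace = trace, train_x = st$train_x,
                 train_y = st$train_y, pool_x = st$pool_x,
                 pool_ids = st$pool_ids),
            class = "al_run")
}

#' Dispatch an active-learning run by strategy name
#'
#' @param name One of `"al_us"`, `"al_qbc"`, `"al_er"`, `"al_acr"`,
#'   `"aldc_us"`, `"aldc_qbc"`, `"aldc_er"`, `"random"`.
#' @param ... Passed to the matching runner.
#' @return An `al_run` list.
#' @export
run_strategy <- function(name, ...) {
  switch(name,
         al_us = run_baseline(..., strategy = "us"),
         al_qbc = run_baseline(..., strategy = "qbc"),
         al_er = run_baseline(..., strategy = "er"),
         al_acr = run_acr(...),
         aldc_us = run_aldc(..., strategy = "us"),
         aldc_qbc = run_aldc(..., strategy = "qbc"),
         aldc_er = run_aldc(..., strategy = "er"),
         random = run_random(...),
         stop("unknown strategy: ", name))
}
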