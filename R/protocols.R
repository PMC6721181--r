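#' Recognition accuracy on one batch
#'
#' @param predictions,truths Equal-length label vectors.
#' @return Fraction of correct predictions in `[0, 1]`.
#' @export
accuracy_batch <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L)
    stop("predictions and truths must be non-empty and of equal length")
  mean(as.character(predictions) == as.character(truths))
}

#' Recognition accuracy over the data pool and the test set together
#'
#' Pools the correct counts of both partitions over their combined size,
#' the batch-level accuracy used once selected instances have been
#' removed from the pool. With an empty pool it reduces to the plain
#' test-set accuracy.
#'
#' @param pred_pool,truth_pool Predictions and truths on the (remaining)
#'   data pool; may be empty.
#' @param pred_test,truth_test Predictions and truths on the test set.
#' @return Combined accuracy in `[0, 1]`.
#' @export
accuracy_pool_plus_test <- function(pred_pool, truth_pool,
                                    pred_test, truth_test) {
  if (length(pred_pool) != length(truth_pool) ||
      length(pred_test) != length(truth_test))
    stop("prediction/truth lengths differ")
  n <- length(truth_pool) + length(truth_test)
  if (n == 0L) stop("empty pool and test set")
  correct <- sum(as.character(pred_pool) == as.character(truth_pool)) +
    sum(as.character(pred_test) == as.character(truth_test))
  correct / n
}

#' Label efficiency index
#'
#' Blends the accuracy level reached before the last update with the
#' accuracy increment that update bought:
#' `LEI = alpha * A + (1 - alpha) * deltaA`. Larger values mean the
#' labelling budget is being spent efficiently. `alpha = 0.5` weighs
#' level and increment equally.
#'
#' @param A Accuracy before the last update, in `[0, 1]`.
#' @param deltaA Accuracy increment caused by the last labeled instance.
#' @param alpha Blend weight in `[0, 1]`.
#' @return The index value.
#' @examples
#' lei(0.8, 0.1, 0.5)  # 0.45
#' @export
lei <- function(A, deltaA, alpha = 0.5) {
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must lie in [0, 1]")
  alpha * A + (1 - alpha) * deltaA
}

#' Build a run configuration
#'
#' Collects every knob of a protocol run in one list: the selection
#' strategy, the labelling budget per batch, the learner settings, the
#' pool/test split, the evaluation mode and the master seed from which all
#' stochastic steps derive their child seeds.
#'
#' @param strategy Strategy name accepted by [run_strategy()].
#' @param n_select Labels queried per AL round (> 0).
#' @param classifier Learner configuration (see [fit_learner()]).
#' @param pool_fraction Pool share of each batch, in (0, 1); about 1/3
#'   gives the conventional 1:2 pool:test ratio.
#' @param pool_mode `"split"` (disjoint pool and test, default) or
#'   `"whole_batch"` (the pool covers the whole batch and the evaluation
#'   runs on the full batch).
#' @param eval_mode `"test"` (accuracy on the test partition) or
#'   `"pool_plus_test"` (remaining pool and test pooled together).
#' @param normalize Standardize features with initial-training-set
#'   statistics (default FALSE; synthetic features are already on unit
#'   scale).
#' @param accumulate Keep selected samples in the training set across the
#'   rounds of the long-term protocol (default TRUE).
#' @param eval_each_step Record per-step accuracies in the traces
#'   (needed for the label efficiency index; default TRUE).
#' @param metric Uncertainty-metric options (see [pool_uncertainty()]).
#' @param alpha Label-efficiency blend weight.
#' @param seed Master integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(strategy = "aldc_us", n_select = 20L,
                       classifier = list(type = "kelm", gamma = 0.005,
                                         C_reg = 100, k_members = 2L),
                       pool_fraction = 1 / 3,
                       pool_mode = c("split", "whole_batch"),
                       eval_mode = c("test", "pool_plus_test"),
                       normalize = FALSE, accumulate = TRUE,
                       eval_each_step = TRUE, metric = list(loss = "log",
                                                            pool_cap = 200L),
                       alpha = 0.5, seed = 1L) {
  if (n_select < 1L) stop("n_select must be positive")
  if (!(pool_fraction > 0 && pool_fraction < 1))
    stop("pool_fraction must lie in (0, 1)")
  structure(list(strategy = strategy, n_select = as.integer(n_select),
                 classifier = classifier, pool_fraction = pool_fraction,
                 pool_mode = match.arg(pool_mode),
                 eval_mode = match.arg(eval_mode), normalize = normalize,
                 accumulate = accumulate, eval_each_step = eval_each_step,
                 metric = metric, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# one AL round on a single drifted batch; returns accuracy + trace
al_round <- function(train_x, train_y, batch, cfg, classes, round_seed) {
  if (cfg$pool_mode == "whole_batch") {
    pool <- batch
    test <- batch
  } else {
    sp <- split_pool_test(batch, cfg$pool_fraction, seed = round_seed)
    pool <- sp$pool
    test <- sp$test
  }
  oracle <- make_oracle(pool)
  n_sel <- min(cfg$n_select, batch_size(pool))
  eval_fn <- if (cfg$eval_each_step)
    function(lrn) accuracy_batch(predict(lrn, test$x), test$y)
  run <- run_strategy(cfg$strategy, train_x = train_x, train_y = train_y,
                      pool = pool, oracle = oracle, n_select = n_sel,
                      classifier = cfg$classifier, seed = round_seed,
                      eval_fn = eval_fn, classes = classes,
                      metric = cfg$metric)
  acc <- switch(cfg$eval_mode,
    test = accuracy_batch(predict(run$learner, test$x), test$y),
    pool_plus_test = {
      remaining <- match(run$pool_ids, rownames(pool$x))
      pred_pool <- if (length(remaining))
        predict(run$learner, pool$x[remaining, , drop = FALSE]) else character(0)
      accuracy_pool_plus_test(pred_pool, pool$y[remaining],
                              predict(run$learner, test$x), test$y)
    })
  list(run = run, accuracy = acc, n_pool = batch_size(pool),
       n_test = batch_size(test))
}

#' Long-term drift protocol
#'
#' The first batch is the fully labeled initial training set; every
#' subsequent batch triggers one active-learning round (pool/test split,
#' `n_select` label queries, learner update, evaluation), so a B-batch
#' sequence yields B - 1 rounds. By default the queried samples
#' accumulate in the training set across rounds, modeling a deployed
#' system that keeps every label it ever bought.
#'
#' @param seq A [drift_batch_seq()] with >= 2 batches whose first batch
#'   covers every class.
#' @param cfg A [run_config()].
#' @return A list of class `drift_protocol_result`: `setting`,
#'   `strategy`, `batch_results` (data.frame: batch_id, n_pool, n_test,
#'   accuracy), `traces` (one per round), `config`.
#' @export
run_setting1 <- function(seq, cfg) {
  batches <- seq$batches
  if (length(batches) < 2L) stop("need at least 2 batches")
  classes <- seq$label_set
  if (!all(classes %in% batches[[1]]$y))
    stop("the initial training batch must cover every class")
  if (cfg$normalize) {
    nf <- normalize_features(batches[[1]], batches[-1])
    batches <- c(list(nf$train), nf$others)
  }
  train_x <- batches[[1]]$x
  train_y <- batches[[1]]$y
  rows <- list(); traces <- list()
  for (b in 2:length(batches)) {
    rs <- derive_seed(cfg$seed, "s1", b)
    out <- al_round(train_x, train_y, batches[[b]], cfg, classes, rs)
    rows[[b - 1]] <- data.frame(batch_id = batches[[b]]$batch_id,
                                n_pool = out$n_pool, n_test = out$n_test,
                                accuracy = out$accuracy)
    traces[[b - 1]] <- out$run$trace
    if (cfg$accumulate) {
      train_x <- out$run$train_x
      train_y <- out$run$train_y
    }
  }
  structure(list(setting = 1L, strategy = cfg$strategy,
                 batch_results = do.call(rbind, rows),
                 traces = traces, config = cfg),
            class = "drift_protocol_result")
}

#' Short-term drift protocol
#'
#' Every consecutive batch pair (b, b+1) is an independent scenario: the
#' former batch is the fully labeled training set, the latter supplies
#' the pool and test data for one active-learning round. Nothing carries
#' over between pairs, so a B-batch sequence yields B - 1 isolated
#' rounds.
#'
#' @inheritParams run_setting1
#' @return A `drift_protocol_result` (same layout as [run_setting1()],
#'   `setting = 2`).
#' @export
run_setting2 <- function(seq, cfg) {
  batches <- seq$batches
  if (length(batches) < 2L) stop("need at least 2 batches")
  classes <- seq$label_set
  rows <- list(); traces <- list()
  for (b in 2:length(batches)) {
    former <- batches[[b - 1]]; latter <- batches[[b]]
    if (!all(unique(latter$y) %in% unique(former$y)))
      stop("former batch ", former$batch_id,
           " does not cover the classes of batch ", latter$batch_id)
    if (cfg$normalize) {
      nf <- normalize_features(former, list(latter))
      former <- nf$train; latter <- nf$others[[1]]
    }
    cls <- sort(unique(former$y))
    rs <- derive_seed(cfg$seed, "s2", b)
    out <- al_round(former$x, former$y, latter, cfg, cls, rs)
    rows[[b - 1]] <- data.frame(batch_id = latter$batch_id,
                                n_pool = out$n_pool, n_test = out$n_test,
                                accuracy = out$accuracy)
    traces[[b - 1]] <- out$run$trace
  }
  structure(list(setting = 2L, strategy = cfg$strategy,
                 batch_results = do.call(rbind, rows),
                 traces = traces, config = cfg),
            class = "drift_protocol_result")
}

#' @export
print.drift_protocol_result <- function(x, ...) {
  cat(sprintf("<drift protocol: setting %d, strategy %s, %d rounds, mean accuracy %.4f>\n",
              x$setting, x$strategy, nrow(x$batch_results),
              mean(x$batch_results$accuracy)))
  invisible(x)
}

#' Static (never-updated) learner baseline over a batch sequence
#'
#' Trains once on the first batch (or, for the short-term setting, each
#' former batch) and evaluates each subsequent batch without any label
#' queries, quantifying how much drift degrades an uncorrected learner.
#'
#' @inheritParams run_setting1
#' @param setting 1 (fixed initial training set) or 2 (per-pair training
#'   set).
#' @return Data frame with `batch_id` and `accuracy`.
#' @export
run_static_baseline <- function(seq, cfg, setting = 1L) {
  batches <- seq$batches
  if (cfg$normalize) {
    nf <- normalize_features(batches[[1]], batches[-1])
    batches <- c(list(nf$train), nf$others)
  }
  rows <- list()
  learner <- fit_learner(batches[[1]]$x, batches[[1]]$y, cfg$classifier)
  for (b in 2:length(batches)) {
    if (setting == 2L && b > 2L)
      learner <- fit_learner(batches[[b - 1]]$x, batches[[b - 1]]$y,
                             cfg$classifier)
    target <- batches[[b]]
    if (cfg$pool_mode == "split") {
      sp <- split_pool_test(target, cfg$pool_fraction,
                            seed = derive_seed(cfg$seed, paste0("s", setting), b))
      eval_b <- if (cfg$eval_mode == "test") sp$test else target
    } else eval_b <- target
    rows[[b - 1]] <- data.frame(batch_id = target$batch_id,
                                accuracy = accuracy_batch(predict(learner, eval_b$x),
                                                          eval_b$y))
  }
  do.call(rbind, rows)
}

#' Label-efficiency sweep over selection budgets
#'
#' Runs the chosen protocol once with the largest budget in `n_range` and
#' slices its per-step accuracy traces: because selection is greedy and
#' sequential, the first `N` queries of a budget-`max(n_range)` run are
#' exactly the budget-`N` run. For each `N`, `A` is the test accuracy
#' before the N-th update and `deltaA` the increment that update caused;
#' the label efficiency index is averaged over the protocol's rounds.
#'
#' @param seq A [drift_batch_seq()].
#' @param cfg A [run_config()] (its `n_select` is overridden by
#'   `max(n_range)`; `eval_each_step` is forced on).
#' @param n_range Integer vector of budgets to report.
#' @param setting 1 (long-term) or 2 (short-term).
#' @return Data frame with columns `n`, `A`, `deltaA`, `lei` (one row per
#'   budget, averaged over rounds).
#' @export
lei_sweep <- function(seq, cfg, n_range = 11:20, setting = 1L) {
  n_range <- sort(as.integer(n_range))
  cfg$n_select <- max(n_range)
  cfg$eval_each_step <- TRUE
  res <- if (setting == 1L) run_setting1(seq, cfg) else run_setting2(seq, cfg)
  rows <- lapply(n_range, function(N) {
    per_round <- vapply(res$traces, function(tr) {
      if (nrow(tr) < N) return(c(NA_real_, NA_real_))
      A <- tr$acc_before[N]
      dA <- tr$acc_after[N] - tr$acc_before[N]
      c(A, dA)
    }, numeric(2))
    A <- mean(per_round[1, ], na.rm = TRUE)
    dA <- mean(per_round[2, ], na.rm = TRUE)
    data.frame(n = N, A = A, deltaA = dA, lei = lei(A, dA, cfg$alpha))
  })
  do.call(rbind, rows)
}
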