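test_that("batch accuracy and pooled accuracy follow their definitions", {
  expect_equal(accuracy_batch(c("a", "b", "a", "a"), c("a", "b", "b", "a")), 0.75)
  expect_equal(accuracy_batch(c("a", "a"), c("a", "a")), 1)
  expect_equal(accuracy_batch(c("a", "a"), c("b", "b")), 0)
  expect_error(accuracy_batch(character(0), character(0)), "non-empty")
  expect_equal(accuracy_pool_plus_test(c("a", "b"), c("a", "a"),
                                       c("x", "x", "x", "y"),
                                       c("x", "x", "x", "x")), 4 / 6)
  # empty pool: reduces to the plain batch accuracy
  p <- c("a", "b", "a"); t <- c("a", "b", "b")
  expect_equal(accuracy_pool_plus_test(character(0), character(0), p, t),
               accuracy_batch(p, t))
  expect_equal(accuracy_pool_plus_test(c("a"), c("a"), c("b"), c("b")), 1)
})

test_that("the label efficiency index blends level and increment", {
  expect_equal(lei(0.8, 0.1, 0.5), 0.45)
  expect_equal(lei(0.7, 0.2, 1), 0.7)
  expect_equal(lei(0.7, 0.2, 0), 0.2)
  expect_error(lei(0.5, 0, 1.2), "alpha")
  # range given A in [0,1], deltaA in [-1,1]
  set.seed(5)
  for (i in 1:50) {
    v <- lei(runif(1), runif(1, -1, 1), 0.5)
    expect_gte(v, -0.5)
    expect_lte(v, 1)
  }
})

make_toy_seq <- function(n_batches, seed = 1, drift = 0.4) {
  spec <- drift_spec(n_classes = 3, n_dim = 3, n_batches = n_batches,
                     batch_sizes = 36, class_sep = 4,
                     drift_common = drift, drift_class = drift / 2,
                     noise_sd = 0.8, imbalance = Inf, seed = seed)
  generate_drift_sequence(spec)
}

toy_cfg <- function(...) {
  defaults <- list(classifier = toy_classifier, n_select = 3,
                   eval_each_step = FALSE)
  do.call(run_config, utils::modifyList(defaults, list(...)))
}

test_that("a B-batch sequence triggers B-1 rounds under both protocols", {
  s <- make_toy_seq(5)
  cfg <- toy_cfg(strategy = "aldc_us", seed = 3)
  r1 <- run_setting1(s, cfg)
  expect_equal(nrow(r1$batch_results), 4)
  expect_equal(r1$batch_results$batch_id, 2:5)
  r2 <- run_setting2(s, cfg)
  expect_equal(nrow(r2$batch_results), 4)
  s2 <- make_toy_seq(2)
  expect_equal(nrow(run_setting1(s2, cfg)$batch_results), 1)
  expect_true(all(r1$batch_results$accuracy >= 0 &
                  r1$batch_results$accuracy <= 1))
  # default split honors the ~1:2 pool:test ratio
  expect_equal(r1$batch_results$n_pool, rep(12, 4))
  expect_equal(r1$batch_results$n_test, rep(24, 4))
})

test_that("protocol results are bit-for-bit reproducible under one seed", {
  s <- make_toy_seq(4)
  cfg <- toy_cfg(strategy = "aldc_qbc", seed = 11, eval_each_step = TRUE)
  a <- run_setting1(s, cfg)
  b <- run_setting1(s, cfg)
  expect_identical(a$batch_results, b$batch_results)
  expect_identical(a$traces, b$traces)
})

test_that("short-term rounds are isolated from later batches", {
  s <- make_toy_seq(5, seed = 2)
  cfg <- toy_cfg(strategy = "al_us", seed = 7)
  full <- run_setting2(s, cfg)
  # permute the tail of the sequence: the first pair's result is unchanged
  perm <- drift_batch_seq(list(s$batches[[1]], s$batches[[2]],
                               s$batches[[5]], s$batches[[4]],
                               s$batches[[3]]) |>
                            (\(l) { for (i in seq_along(l)) l[[i]]$batch_id <- i; l })(),
                          label_set = s$label_set)
  permres <- run_setting2(perm, cfg)
  expect_equal(permres$batch_results$accuracy[1],
               full$batch_results$accuracy[1])
})

test_that("training on a batch and selecting from its twin is near-perfect", {
  b <- make_blobs(n_per = 15, K = 3, D = 3, sep = 8, sd = 0.5, seed = 12)
  twin <- drift_batch(b$x, y = b$y, batch_id = 2L,
                      ids = paste0("t_", seq_len(nrow(b$x))))
  s <- drift_batch_seq(list(b, twin))
  cfg <- toy_cfg(strategy = "aldc_us", seed = 1)
  r <- run_setting2(s, cfg)
  expect_gte(r$batch_results$accuracy, 0.99)
})

test_that("the static baseline never queries labels and accuracy reflects drift", {
  s <- make_toy_seq(6, seed = 4, drift = 1.5)
  cfg <- toy_cfg(strategy = "al_us", seed = 2)
  st <- run_static_baseline(s, cfg, setting = 1L)
  expect_equal(nrow(st), 5)
  al <- run_setting1(s, cfg)
  expect_gt(mean(al$batch_results$accuracy), mean(st$accuracy))
})

test_that("the efficiency sweep slices one max-budget run per budget", {
  s <- make_toy_seq(3, seed = 6, drift = 1.2)
  cfg <- toy_cfg(strategy = "aldc_us", seed = 9)
  tab <- lei_sweep(s, cfg, n_range = c(2, 4), setting = 1L)
  expect_equal(tab$n, c(2L, 4L))
  # hand recomputation from the traces of the same run
  cfg$n_select <- 4L; cfg$eval_each_step <- TRUE
  res <- run_setting1(s, cfg)
  for (row in 1:2) {
    N <- tab$n[row]
    A <- mean(vapply(res$traces, function(tr) tr$acc_before[N], numeric(1)))
    dA <- mean(vapply(res$traces,
                      function(tr) tr$acc_after[N] - tr$acc_before[N],
                      numeric(1)))
    expect_equal(tab$A[row], A, tolerance = 1e-12)
    expect_equal(tab$lei[row], 0.5 * A + 0.5 * dA, tolerance = 1e-12)
  }
  tab1 <- lei_sweep(s, cfg, n_range = 3, setting = 2L)
  expect_equal(nrow(tab1), 1)
})

test_that("a run whose accuracy never moves has LEI = alpha * A", {
  # no drift, perfectly separable: accuracy pinned at 1, increment 0
  b1 <- make_blobs(n_per = 12, K = 2, D = 2, sep = 10, sd = 0.3, seed = 3)
  b2 <- make_blobs(n_per = 12, K = 2, D = 2, sep = 10, sd = 0.3, seed = 3,
                   batch_id = 2)
  s <- drift_batch_seq(list(b1, b2))
  cfg <- toy_cfg(strategy = "al_us", seed = 5)
  tab <- lei_sweep(s, cfg, n_range = 2:3)
  expect_equal(tab$deltaA, c(0, 0))
  expect_equal(tab$lei, 0.5 * tab$A)
  expect_equal(tab$A, c(1, 1))
})

test_that("whole-batch pool mode evaluates on the full batch", {
  s <- make_toy_seq(3, seed = 8)
  cfg <- run_config(strategy = "al_us", n_select = 3,
                    classifier = toy_classifier, pool_mode = "whole_batch",
                    eval_each_step = FALSE, seed = 1)
  r <- run_setting1(s, cfg)
  expect_equal(r$batch_results$n_pool, rep(36, 2))
  expect_equal(r$batch_results$n_test, rep(36, 2))
})

test_that("YAML configs map onto run_config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("strategy: aldc_er", "n_select: 7", "seed: 42",
               "pool_fraction: 0.25",
               "classifier:", "  type: kelm", "  gamma: 0.01"), f)
  cfg <- read_run_config(f)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$strategy, "aldc_er")
  expect_equal(cfg$n_select, 7L)
  expect_equal(cfg$pool_fraction, 0.25)
  expect_equal(cfg$classifier$gamma, 0.01)
})
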