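test_that("class means equal per-class averages", {
  x <- rbind(c(0, 0), c(2, 2), c(5, 1))
  m <- init_class_means(x, c("A", "A", "B"))
  expect_equal(unname(m["A", ]), c(1, 1))
  expect_equal(unname(m["B", ]), c(5, 1))
  set.seed(13)
  x2 <- matrix(rnorm(40), 20, 2)
  y2 <- sample(c("a", "b", "c"), 20, replace = TRUE)
  while (length(unique(y2)) < 3) y2 <- sample(c("a", "b", "c"), 20, TRUE)
  m2 <- init_class_means(x2, y2)
  for (cl in c("a", "b", "c"))
    expect_equal(unname(m2[cl, ]), colMeans(x2[y2 == cl, , drop = FALSE]))
  expect_error(init_class_means(x2, y2, classes = c("a", "b", "c", "d")),
               "no sample of class: d")
})

test_that("clustering reaches stated fixed points and handles empty clusters", {
  pool <- matrix(c(0, 1, 9, 10))
  cs <- cluster_pool(pool, matrix(c(0.5, 9.5)))
  expect_equal(cs$assignment, c(1, 1, 2, 2))
  expect_equal(unname(cs$means[, 1]), c(0.5, 9.5))
  # single point: joins the nearer seed, the other cluster keeps its seed
  cs2 <- cluster_pool(matrix(1.2), matrix(c(1, 50)))
  expect_equal(cs2$assignment, 1L)
  expect_equal(unname(cs2$means[2, ]), 50)
  expect_equal(cs2$counts, c(1L, 0L))
})

test_that("clustering agrees with independent Lloyd implementations", {
  set.seed(31)
  for (rep in 1:5) {
    b <- make_blobs(n_per = 15, K = 3, D = 2, sep = 6, sd = 1, seed = rep)
    seeds <- init_class_means(b$x, b$y)
    cs <- cluster_pool(b$x, seeds)
    naive <- oracle_lloyd(b$x, seeds)
    expect_equal(cs$assignment, naive$assignment)
    expect_equal(cs$means, naive$means, tolerance = 1e-9)
    km <- suppressWarnings(stats::kmeans(b$x, centers = seeds,
                                         algorithm = "Lloyd", iter.max = 100))
    expect_equal(unname(cs$assignment), unname(km$cluster))
  }
})

test_that("within-cluster sum of squares never increases across iterations", {
  set.seed(17)
  for (rep in 1:10) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    seeds <- matrix(rnorm(4 * 3, sd = 2), 4, 3)
    cs <- cluster_pool(x, seeds)
    expect_true(all(diff(cs$wss_trace) <= 1e-9))
    expect_lte(cs$iterations, 100L)
  }
})

test_that("cluster selection follows flag-masked mean uncertainty", {
  st <- structure(list(assignment = c(1, 1, 2, 2), counts = c(2L, 2L)),
                  class = "cluster_state")
  scores <- c(0.2, 0.2, 0.5, 0.5)
  expect_equal(select_cluster(st, scores, c(1, 1)), 2L)
  expect_equal(select_cluster(st, scores, c(1, 0)), 1L)
  expect_error(select_cluster(st, scores, c(0, 0)), "reset")
  # brute-force agreement on random configurations
  set.seed(23)
  for (rep in 1:20) {
    K <- sample(2:5, 1); n <- 20
    assign <- sample(seq_len(K), n, replace = TRUE)
    sc <- runif(n)
    flags <- rbinom(K, 1, 0.7)
    if (all(flags == 0)) flags[1] <- 1
    st <- structure(list(assignment = assign,
                         counts = tabulate(assign, nbins = K)),
                    class = "cluster_state")
    vals <- vapply(seq_len(K), function(k) {
      if (flags[k] == 0 || sum(assign == k) == 0) return(-Inf)
      mean(sc[assign == k])
    }, numeric(1))
    if (all(!is.finite(vals))) {
      expect_error(select_cluster(st, sc, flags), "eligible")
    } else {
      expect_equal(select_cluster(st, sc, flags), which.max(vals))
      k <- select_cluster(st, sc, flags)
      members <- which(assign == k)
      expect_equal(select_instance_in_cluster(st, k, sc),
                   members[which.max(sc[members])])
    }
  }
  expect_error(select_instance_in_cluster(
    structure(list(assignment = c(1, 1), counts = c(2L, 0L)),
              class = "cluster_state"), 2, c(0.1, 0.2)), "empty")
})

test_that("flags clear on selection and reset exactly when all are zero", {
  f <- update_flags(c(1, 1, 1), 2)
  expect_equal(f, c(1, 0, 1))
  expect_equal(update_flags(c(0, 0, 1), 3), c(1, 1, 1))
  expect_error(update_flags(c(1, 0, 1), 2), "flag 0")
})

test_that("the dynamic-clustering loop conserves instances and alternates clusters", {
  sc <- random_scenario(3, K = 3, n_pool = 12, D = 3)
  n0_train <- nrow(sc$train_x); n0_pool <- nrow(sc$pool$x)
  run <- run_aldc(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool),
                  n_select = 12, strategy = "us", classifier = toy_classifier)
  expect_equal(nrow(run$train_x), n0_train + 12)
  expect_equal(nrow(run$pool_x), 0)
  expect_equal(length(unique(run$trace$id)), 12)      # no instance re-selected
  expect_setequal(run$trace$id, rownames(sc$pool$x))  # pool fully consumed
  expect_equal(run$trace$step, 1:12)
  # cluster alternation while all clusters stay populated: the first two
  # flag cycles each visit all three clusters exactly once
  cl <- run$trace$cluster
  expect_setequal(cl[1:3], 1:3)
  expect_setequal(cl[4:6], 1:3)
})

test_that("a zero budget leaves the learner and pool untouched", {
  sc <- random_scenario(4, K = 2, n_pool = 6, D = 2)
  run <- run_aldc(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool),
                  n_select = 0, strategy = "us", classifier = toy_classifier)
  expect_equal(nrow(run$trace), 0)
  expect_equal(nrow(run$train_x), nrow(sc$train_x))
  expect_equal(length(run$pool_ids), nrow(sc$pool$x))
  expect_error(run_aldc(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool),
                        n_select = 7, strategy = "us"), "exceeds")
})

test_that("with aligned clusters the first K selections cover all K classes", {
  for (seed in 1:5) {
    b1 <- make_blobs(n_per = 8, K = 4, D = 3, sep = 8, sd = 0.5, seed = seed)
    b2 <- make_blobs(n_per = 6, K = 4, D = 3, sep = 8, sd = 0.5,
                     seed = seed, batch_id = 2)
    run <- run_aldc(b1$x, b1$y, b2, make_oracle(b2), n_select = 4,
                    strategy = "us", classifier = toy_classifier)
    expect_setequal(run$trace$label, paste0("c", 1:4))
  }
})

test_that("uncertainty sampling picks the most ambiguous instance first", {
  train_x <- matrix(c(-4, -3.5, 3.5, 4)); train_y <- c("a", "a", "b", "b")
  pool <- drift_batch(matrix(c(-3.9, 0, 3.9)), y = c("a", "a", "b"),
                      batch_id = 2)
  run <- run_baseline(train_x, train_y, pool, make_oracle(pool), 1,
                      strategy = "us", classifier = toy_classifier)
  expect_equal(run$trace$id, rownames(pool$x)[2])  # the midpoint
})

test_that("identical committee members give all-zero disagreement, ties to index 1", {
  tiny <- make_blobs(n_per = 1, K = 2, D = 2, seed = 6)  # degenerate bootstrap
  pool <- make_blobs(n_per = 4, K = 2, D = 2, seed = 7, batch_id = 2)
  run <- run_baseline(tiny$x, tiny$y, pool, make_oracle(pool), 1,
                      strategy = "qbc", classifier = toy_classifier)
  expect_equal(run$trace$id, rownames(pool$x)[1])
  expect_lt(run$trace$uncertainty, 1e-9)
})

test_that("selection sequences are reproducible under a fixed seed", {
  sc <- random_scenario(9, K = 3, n_pool = 12, D = 3)
  r1 <- run_aldc(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool), 5,
                 strategy = "qbc", classifier = toy_classifier, seed = 77)
  r2 <- run_aldc(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool), 5,
                 strategy = "qbc", classifier = toy_classifier, seed = 77)
  expect_identical(r1$trace, r2$trace)
  r3 <- run_acr(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool), 5,
                classifier = toy_classifier, seed = 77)
  r4 <- run_acr(sc$train_x, sc$train_y, sc$pool, make_oracle(sc$pool), 5,
                classifier = toy_classifier, seed = 77)
  expect_identical(r3$trace, r4$trace)
})

test_that("each strategy matches its brute-force oracle on small scenarios", {
  cases <- list(list(strategy = "al_us", seed = 101, K = 2, n_pool = 12),
                list(strategy = "aldc_us", seed = 102, K = 3, n_pool = 15),
                list(strategy = "al_qbc", seed = 103, K = 3, n_pool = 10),
                list(strategy = "al_acr", seed = 104, K = 2, n_pool = 10),
                list(strategy = "al_er", seed = 105, K = 2, n_pool = 7))
  for (cs in cases) {
    sc <- random_scenario(cs$seed, K = cs$K, n_pool = cs$n_pool, D = 3)
    got <- run_strategy(cs$strategy, train_x = sc$train_x, train_y = sc$train_y,
                        pool = sc$pool, oracle = make_oracle(sc$pool),
                        n_select = 3, classifier = toy_classifier, seed = 55,
                        metric = list(loss = "log", pool_cap = 1000L))
    want <- oracle_select_sequence(cs$strategy, sc$train_x, sc$train_y,
                                   sc$pool, 3, seed = 55,
                                   classifier = toy_classifier)
    expect_equal(got$trace$id, want, info = cs$strategy)
  }
})
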