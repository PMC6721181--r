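# Small in-code fixtures shared across the suite.

# well-separated Gaussian blobs, one per class
make_blobs <- function(n_per = 10L, K = 2L, D = 2L, sep = 8, sd = 0.5,
                       seed = 1L, batch_id = 1L) {
  set.seed(seed)
  mu <- matrix(rnorm(K * D, sd = sep), K, D)
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(n_per * D, sd = sd), n_per, D) +
      matrix(mu[k, ], n_per, D, byrow = TRUE)))
  drift_batch(x, y = rep(paste0("c", seq_len(K)), each = n_per),
              batch_id = batch_id)
}

# a labeled train set plus a pool drawn from slightly shifted blobs
random_scenario <- function(seed, K = 3L, n_pool = 15L, n_train_per = 3L,
                            D = 3L) {
  set.seed(seed)
  mu <- matrix(rnorm(K * D, sd = 4), K, D)
  shift <- matrix(rnorm(K * D, sd = 1), K, D)
  train_x <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(n_train_per * D), n_train_per, D) +
      matrix(mu[k, ], n_train_per, D, byrow = TRUE)))
  train_y <- rep(paste0("c", seq_len(K)), each = n_train_per)
  per <- diff(round(seq(0, n_pool, length.out = K + 1)))
  pool_x <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(per[k] * D), per[k], D) +
      matrix(mu[k, ] + shift[k, ], per[k], D, byrow = TRUE)))
  pool_y <- rep(paste0("c", seq_len(K)), per)
  ord <- sample.int(nrow(pool_x))
  list(train_x = train_x, train_y = train_y,
       pool = drift_batch(pool_x[ord, , drop = FALSE], y = pool_y[ord],
                          batch_id = 2L),
       classes = paste0("c", seq_len(K)))
}

# random point on the probability simplex
random_simplex <- function(K) {
  g <- rexp(K)
  g / sum(g)
}

# a fast learner configuration for tiny fixtures (wider kernel suits
# unit-scale toy coordinates better than the benchmark default)
toy_classifier <- list(type = "kelm", gamma = 0.1, C_reg = 100)
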