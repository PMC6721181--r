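# Independent brute-force oracles. These transcribe the defining formulas
# naively (explicit loops, literal forms) and never call the package's
# scoring/clustering/selection code paths. Posteriors are taken from the
# package's learners: the quantities under test are the selection rules
# and closed-form metrics, not the classifier.

oracle_margin <- function(p) {
  s <- sort(p, decreasing = TRUE)
  s[1] - s[2]
}

# literal mean-of-members form: D_k = sum_m Pk_m * log(K * Pk_m / sum_k Pk_m)
oracle_kld <- function(P) {
  K <- nrow(P)
  tot <- 0
  for (k in seq_len(K)) {
    d <- 0
    for (m in seq_len(ncol(P))) {
      pk <- P[k, m]
      if (pk > 0) d <- d + pk * log(K * pk / sum(P[, m]))
    }
    tot <- tot + d
  }
  tot / K
}

oracle_log_loss <- function(P) {
  tot <- 0
  for (i in seq_len(nrow(P)))
    for (m in seq_len(ncol(P))) {
      p <- P[i, m]
      if (p > 0) tot <- tot + p * log(1 / p)
    }
  tot / nrow(P)
}

oracle_zero_one_loss <- function(P) {
  tot <- 0
  for (i in seq_len(nrow(P))) tot <- tot + 1 - max(P[i, ])
  tot / nrow(P)
}

# naive Lloyd iteration with explicit distance loops
oracle_lloyd <- function(x, means, tol = 1e-6, max_iter = 100L) {
  assign <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(x))) {
      dists <- vapply(seq_len(nrow(means)), function(k)
        sqrt(sum((x[i, ] - means[k, ])^2)), numeric(1))
      assign[i] <- which.min(dists)
    }
    new_means <- means
    for (k in seq_len(nrow(means)))
      if (any(assign == k))
        new_means[k, ] <- colMeans(x[assign == k, , drop = FALSE])
    shift <- max(sqrt(rowSums((new_means - means)^2)))
    means <- new_means
    if (shift < tol) break
  }
  list(assignment = assign, means = means)
}

oracle_er <- function(i, learner, train_x, train_y, px, classifier,
                      eps = 1e-12) {
  rest <- setdiff(seq_len(nrow(px)), i)
  if (!length(rest)) return(eps)
  cur <- oracle_log_loss(predict_proba(learner, px[rest, , drop = FALSE]))
  post <- predict_proba(learner, px[i, , drop = FALSE])[1, ]
  expected <- 0
  for (cl in names(post)) {
    if (post[[cl]] == 0) next
    rf <- fit_learner(rbind(train_x, px[i, , drop = FALSE]),
                      c(train_y, cl), classifier)
    expected <- expected + post[[cl]] *
      oracle_log_loss(predict_proba(rf, px[rest, , drop = FALSE]))
  }
  max(cur - expected, eps)
}

# full re-evaluation of a selection sequence, strategy by strategy
oracle_select_sequence <- function(strategy, train_x, train_y, pool, n,
                                   classes = sort(unique(as.character(train_y))),
                                   seed = 1L,
                                   classifier = list(type = "kelm"),
                                   eps = 1e-12) {
  px <- pool$x
  ids <- rownames(pool$x)
  ask <- make_oracle(pool)
  train_y <- as.character(train_y)
  flags <- rep(1, length(classes))
  learner <- fit_learner(train_x, train_y, classifier)
  needs_cmt <- strategy %in% c("al_qbc", "aldc_qbc", "al_acr")
  committee <- if (needs_cmt)
    build_committee(train_x, train_y, seed = derive_seed(seed, "cmt", 0),
                    classifier = classifier)
  changed <- NA
  picked <- character(0)
  for (step in seq_len(n)) {
    scores <- numeric(nrow(px))
    if (strategy %in% c("al_us", "aldc_us")) {
      for (i in seq_len(nrow(px)))
        scores[i] <- 1 - oracle_margin(predict_proba(learner, px[i, , drop = FALSE])[1, ]) + eps
    } else if (needs_cmt) {
      for (i in seq_len(nrow(px))) {
        P <- do.call(rbind, lapply(committee$members, function(m)
          predict_proba(m, px[i, , drop = FALSE])[1, ]))
        s_i <- oracle_kld(P)
        if (s_i < 1e-12) s_i <- 0
        scores[i] <- s_i + if (strategy == "al_acr") 0 else eps
      }
    } else {
      for (i in seq_len(nrow(px)))
        scores[i] <- oracle_er(i, learner, train_x, train_y, px, classifier, eps)
    }
    if (startsWith(strategy, "aldc")) {
      means <- t(sapply(classes, function(cl)
        colMeans(train_x[train_y == cl, , drop = FALSE])))
      cl_state <- oracle_lloyd(px, means)
      vals <- rep(-Inf, length(classes))
      for (k in seq_along(classes))
        if (flags[k] == 1 && sum(cl_state$assignment == k) > 0)
          vals[k] <- mean(scores[cl_state$assignment == k])
      if (all(!is.finite(vals))) {
        flags[] <- 1
        for (k in seq_along(classes))
          if (sum(cl_state$assignment == k) > 0)
            vals[k] <- mean(scores[cl_state$assignment == k])
      }
      kstar <- which.max(vals)
      members <- which(cl_state$assignment == kstar)
      istar <- members[which.max(scores[members])]
      flags[kstar] <- 0
      if (all(flags == 0)) flags[] <- 1
    } else if (strategy == "al_acr") {
      istar <- if (isFALSE(changed)) which.min(scores) else which.max(scores)
    } else {
      istar <- which.max(scores)
    }
    picked <- c(picked, ids[istar])
    lab <- ask(ids[istar])
    train_x <- rbind(train_x, px[istar, , drop = FALSE])
    train_y <- c(train_y, lab)
    px_next <- px[-istar, , drop = FALSE]
    ids <- ids[-istar]
    if (strategy == "al_acr") {
      old_chair <- committee$chair
      committee <- build_committee(train_x, train_y,
                                   seed = derive_seed(seed, "cmt", step),
                                   classifier = classifier)
      changed <- if (nrow(px_next) > 0)
        any(predict(old_chair, px_next) != predict(committee$chair, px_next))
      else NA
    } else {
      learner <- fit_learner(train_x, train_y, classifier)
      if (strategy %in% c("al_qbc", "aldc_qbc"))
        committee <- build_committee(train_x, train_y,
                                     seed = derive_seed(seed, "cmt", step),
                                     classifier = classifier)
    }
    px <- px_next
  }
  picked
}
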