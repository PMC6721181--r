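#' Read a batch file in the sparse "label idx:val" dialect
#'
#' The public gas-sensor drift benchmark stores each measurement as one
#' text line: the class label followed by whitespace-separated
#' `index:value` pairs with 1-based feature indices; absent indices are
#' zero (the libsvm sparse dialect).
#'
#' @param path Path to the text file.
#' @param dimension Feature dimension `D`; every index must be in
#'   `1..dimension`.
#' @param batch_id Batch id to stamp on the result.
#' @return A labeled [drift_batch()].
#' @examples
#' f <- tempfile()
#' writeLines(c("3 1:0.5 4:-1.2", "1"), f)
#' b <- read_batch_file(f, dimension = 4)
#' b$x
#' @export
read_batch_file <- function(path, dimension, batch_id = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  dimension <- as.integer(dimension)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no samples in ", path)
  x <- matrix(0, nrow = length(lines), ncol = dimension)
  y <- character(length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    y[i] <- toks[1]
    if (length(toks) > 1L) {
      pairs <- strsplit(toks[-1], ":", fixed = TRUE)
      bad <- lengths(pairs) != 2L
      if (any(bad)) stop(sprintf("malformed feature token on line %d of %s", i, path))
      idx <- suppressWarnings(as.integer(vapply(pairs, `[[`, "", 1L)))
      val <- suppressWarnings(as.numeric(vapply(pairs, `[[`, "", 2L)))
      if (anyNA(idx) || anyNA(val))
        stop(sprintf("malformed feature token on line %d of %s", i, path))
      if (any(idx < 1L | idx > dimension))
        stop(sprintf("feature index out of range 1..%d on line %d of %s",
                     dimension, i, path))
      x[i, idx] <- val
    }
  }
  drift_batch(x, y = y, batch_id = batch_id)
}

#' Write a batch in the sparse "label idx:val" dialect
#'
#' Zero entries are omitted; values are printed with full double precision
#' so a read/write/read round trip is value-identical.
#'
#' @param batch A labeled [drift_batch()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_batch_file <- function(batch, path) {
  if (is.null(batch$y)) stop("cannot serialize an unlabeled batch")
  lines <- vapply(seq_len(nrow(batch$x)), function(i) {
    v <- batch$x[i, ]
    nz <- which(v != 0)
    if (length(nz))
      paste(batch$y[i], paste0(nz, ":", sprintf("%.17g", v[nz]),
                               collapse = " "))
    else batch$y[i]
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Stratified pool/test split of a batch
#'
#' Splits one drifted batch into an unlabeled data pool (candidates for
#' label querying) and a held-out test set. The split is stratified by
#' class so the pool mirrors the batch's class proportions; the pool
#' receives `floor(pool_fraction * n)` instances in total. A class with
#' fewer than 2 members triggers a fallback to an unstratified split, with
#' a warning.
#'
#' @param batch A labeled [drift_batch()].
#' @param pool_fraction Fraction of the batch assigned to the pool, in
#'   (0, 1). Default 1/3 gives the roughly 1:2 pool:test ratio used in the
#'   batch-wise drift protocols.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with elements `pool` and `test`, both `drift_batch`
#'   objects with disjoint ids. The pool keeps its labels internally (they
#'   back the oracle) but is meant to be treated as unlabeled.
#' @export
split_pool_test <- function(batch, pool_fraction = 1 / 3, seed = 1L) {
  if (!(pool_fraction > 0 && pool_fraction < 1))
    stop("pool_fraction must lie strictly between 0 and 1")
  n <- batch_size(batch)
  n_pool <- floor(pool_fraction * n)
  if (n_pool < 1L) stop("pool_fraction too small: empty pool")
  counts <- table(batch$y)
  set.seed(derive_seed(seed, "split", batch$batch_id))
  if (any(counts < 2L)) {
    warning("class with < 2 members: falling back to unstratified split")
    pool_idx <- sample.int(n, n_pool)
  } else {
    # per-class quota: floor of the ideal, remainder to largest fractions
    ideal <- as.numeric(counts) * pool_fraction
    quota <- floor(ideal)
    rem <- n_pool - sum(quota)
    if (rem > 0) {
      ord <- order(ideal - quota, decreasing = TRUE)
      quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(ideal - quota)
      take <- ord[quota[ord] > 0][seq_len(-rem)]
      quota[take] <- quota[take] - 1L
    }
    pool_idx <- integer(0)
    for (j in seq_along(counts)) {
      members <- which(batch$y == names(counts)[j])
      if (quota[j] > 0)
        pool_idx <- c(pool_idx, sample(members, quota[j]))
    }
  }
  pool_idx <- sort(pool_idx)
  list(pool = subset_batch(batch, pool_idx),
       test = subset_batch(batch, setdiff(seq_len(n), pool_idx)))
}

#' Standardize features using training-set statistics only
#'
#' Per-feature centering and scaling with location and scale estimated on
#' the training batch alone, then applied unchanged to every other batch
#' or pool, so no information leaks from pool or test data into the
#' transform. The scale is the root-mean-square deviation (denominator
#' `n`); a constant feature maps to 0 everywhere.
#'
#' @param train A `drift_batch` supplying the statistics.
#' @param others A list of further `drift_batch` objects to transform with
#'   the training statistics (may be empty).
#' @return A list with `train` (transformed), `others` (list, transformed)
#'   and `stats` (list with `center` and `scale` vectors).
#' @export
normalize_features <- function(train, others = list()) {
  center <- colMeans(train$x)
  dev <- sweep(train$x, 2, center)
  scale <- sqrt(colMeans(dev^2))
  scale[scale == 0] <- Inf  # constant feature -> mapped to 0
  apply_tf <- function(b) {
    z <- sweep(sweep(b$x, 2, center), 2, scale, "/")
    drift_batch(z, y = b$y, batch_id = b$batch_id, ids = rownames(b$x))
  }
  list(train = apply_tf(train),
       others = lapply(others, apply_tf),
       stats = list(center = center, scale = scale))
}
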