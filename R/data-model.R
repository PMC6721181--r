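#' Construct a batch of (optionally labeled) e-nose instances
#'
#' A batch is the unit of drift in the evaluation protocols: a group of
#' measurements recorded in one time period. Each row of `x` is one
#' instance (the feature vector abstracted from a gas-sensor-array
#' measurement); `y`, when present, carries the compound class of each
#' instance.
#'
#' @param x Numeric matrix, one instance per row, `D` columns.
#' @param y Optional vector of class labels (any atomic type), length
#'   `nrow(x)`. Stored as character internally.
#' @param batch_id Integer batch identifier (>= 1).
#' @param ids Optional character vector of unique instance ids; defaults to
#'   `"b<batch_id>_<row>"`.
#' @return An object of class `drift_batch`: a list with elements `x`
#'   (matrix, rownames set to ids), `y` (character or `NULL`) and
#'   `batch_id`.
#' @examples
#' b <- drift_batch(matrix(rnorm(20), 10, 2), y = rep(c("a", "b"), 5))
#' nrow(b$x)
#' @export
drift_batch <- function(x, y = NULL, batch_id = 1L, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stop("a batch must contain at least one instance")
  if (any(!is.finite(x))) stop("feature values must be finite")
  if (!is.null(y)) {
    if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
    y <- as.character(y)
  }
  batch_id <- as.integer(batch_id)
  if (is.null(ids)) ids <- paste0("b", batch_id, "_", seq_len(nrow(x)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("instance ids must be unique within a batch")
  rownames(x) <- ids
  structure(list(x = x, y = y, batch_id = batch_id),
            class = "drift_batch")
}

#' @export
print.drift_batch <- function(x, ...) {
  cat(sprintf("<drift_batch %d: %d instances x %d features%s>\n",
              x$batch_id, nrow(x$x), ncol(x$x),
              if (is.null(x$y)) ", unlabeled"
              else sprintf(", %d classes", length(unique(x$y)))))
  invisible(x)
}

#' Number of instances in a batch
#' @param batch A `drift_batch`.
#' @return Integer count.
#' @export
batch_size <- function(batch) nrow(batch$x)

#' Assemble an ordered sequence of drifting batches
#'
#' @param batches List of `drift_batch` objects with strictly increasing
#'   `batch_id` and a common feature dimension.
#' @param label_set Optional character vector of all classes; defaults to
#'   the sorted union of the batches' labels.
#' @return An object of class `drift_batch_seq` with elements `batches` and
#'   `label_set`.
#' @export
drift_batch_seq <- function(batches, label_set = NULL) {
  stopifnot(length(batches) >= 1L)
  ids <- vapply(batches, function(b) b$batch_id, integer(1))
  if (any(diff(ids) <= 0L)) stop("batch_ids must be strictly increasing")
  dims <- vapply(batches, function(b) ncol(b$x), integer(1))
  if (length(unique(dims)) != 1L) stop("all batches must share one feature dimension")
  seen <- sort(unique(unlist(lapply(batches, function(b) b$y))))
  if (is.null(label_set)) label_set <- seen
  if (!all(seen %in% label_set)) stop("batch labels outside the declared label set")
  structure(list(batches = batches, label_set = as.character(label_set)),
            class = "drift_batch_seq")
}

#' @export
print.drift_batch_seq <- function(x, ...) {
  cat(sprintf("<drift_batch_seq: %d batches, %d classes, D = %d>\n",
              length(x$batches), length(x$label_set), ncol(x$batches[[1]]$x)))
  invisible(x)
}

#' Build a labelling oracle from a labeled batch
#'
#' The oracle stands in for the human expert of the active-learning loop:
#' it returns the true class of an instance on demand, by id. Selection
#' code never touches `batch$y` directly, so the pool behaves as unlabeled
#' data whose labels are purchasable one at a time.
#'
#' @param batch A labeled `drift_batch`.
#' @return A function `f(ids)` mapping instance ids to class labels.
#' @export
make_oracle <- function(batch) {
  if (is.null(batch$y)) stop("cannot build an oracle from an unlabeled batch")
  tab <- batch$y
  names(tab) <- rownames(batch$x)
  function(ids) {
    miss <- setdiff(ids, names(tab))
    if (length(miss)) stop("oracle has no label for id(s): ",
                           paste(miss, collapse = ", "))
    unname(tab[ids])
  }
}

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic steps in the package draw their seed from the run's
#' master seed plus a step-specific key, so one integer reproduces a whole
#' protocol run bit-for-bit.
#'
#' @param seed Master integer seed.
#' @param ... Further atomic keys (strings or integers) identifying the
#'   consuming step.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(keys)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

subset_batch <- function(batch, idx) {
  drift_batch(batch$x[idx, , drop = FALSE],
              y = if (is.null(batch$y)) NULL else batch$y[idx],
              batch_id = batch$batch_id,
              ids = rownames(batch$x)[idx])
}
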