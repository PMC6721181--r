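#' Exponential moving average of a sensor transient's increments
#'
#' The dynamic features of a metal-oxide gas sensor's transient are built
#' from an exponentially smoothed version of the resistance increments:
#' with smoothing coefficient `a` in (0, 1),
#' `y[k] = (1 - a) * y[k-1] + a * (r[k] - r[k-1])`, started at `y[0] = 0`.
#' Small `a` emphasizes slow response dynamics, large `a` fast ones.
#'
#' @param r Numeric resistance time series sampled at uniform steps,
#'   length >= 2 (index k = 0..T).
#' @param a Smoothing coefficient in (0, 1).
#' @return Numeric vector `y` of the same length as `r` (`y[1]`, the k = 0
#'   value, is 0).
#' @examples
#' ema_filter(0:4, a = 0.1)  # 0, 0.1, 0.19, 0.271, ...
#' @export
ema_filter <- function(r, a) {
  if (!(is.numeric(a) && length(a) == 1L && a > 0 && a < 1))
    stop("smoothing coefficient a must lie in (0, 1)")
  if (length(r) < 2L) stop("series must have length >= 2")
  y <- numeric(length(r))
  for (k in 2:length(r))
    y[k] <- (1 - a) * y[k - 1] + a * (r[k] - r[k - 1])
  y
}

#' Extract the 8-feature set of one gas sensor's transient
#'
#' From a single sensor's response curve two steady-state features and six
#' dynamic features are taken: the steady-state response change
#' `dR = max(r) - r[1]` and its baseline-normalized version `dR / r[1]`,
#' plus, for each smoothing coefficient in `a_values`, the maximum of the
#' ema series over the rising stage and the minimum over the decaying
#' stage. The stage boundary defaults to the peak of the response
#' (injection/recovery split).
#'
#' @param r Numeric resistance series, length >= 3.
#' @param b Rising/decaying boundary as a 0-based time index in
#'   `1..(length(r) - 2)`; default `which.max(r) - 1`.
#' @param a_values Smoothing coefficients for the dynamic features.
#' @return Named numeric vector of `2 + 2 * length(a_values)` features:
#'   `dR`, `dR_norm`, `ema_rise_<a>...`, `ema_decay_<a>...`.
#' @export
extract_sensor_features <- function(r, b = NULL,
                                    a_values = c(0.1, 0.01, 0.001)) {
  if (length(r) < 3L) stop("transient must have length >= 3")
  T_end <- length(r) - 1L            # 0-based last index
  # default boundary: peak response, clamped into the valid interior
  if (is.null(b)) b <- min(max(which.max(r) - 1L, 1L), T_end - 1L)
  b <- as.integer(b)
  if (b <= 0L || b >= T_end)
    stop("stage boundary b must satisfy 0 < b < ", T_end)
  if (r[1] == 0) stop("baseline r[0] is zero: normalized response undefined")
  dR <- max(r) - r[1]
  out <- c(dR = dR, dR_norm = dR / r[1])
  rise <- numeric(length(a_values)); decay <- numeric(length(a_values))
  for (j in seq_along(a_values)) {
    y <- ema_filter(r, a_values[j])
    rise[j] <- max(y[2:(b + 1L)])          # k in 1..b
    decay[j] <- min(y[(b + 2L):(T_end + 1L)])  # k in b+1..T
  }
  names(rise) <- paste0("ema_rise_", a_values)
  names(decay) <- paste0("ema_decay_", a_values)
  c(out, rise, decay)
}

#' Map a full sensor array's transients to one feature vector
#'
#' Concatenates [extract_sensor_features()] over the sensors in fixed
#' order; with the conventional 16-sensor array this yields the 128-dim
#' feature vector (8 features x 16 sensors) the drift benchmark uses.
#'
#' @param responses List with one numeric transient per sensor.
#' @param b Optional boundary index shared by all sensors (default:
#'   per-sensor peak).
#' @param a_values Smoothing coefficients, as in
#'   [extract_sensor_features()].
#' @param n_sensors Expected sensor count; an error is raised on mismatch.
#' @return Numeric vector of length `8 * length(responses)` (for the
#'   default three smoothing coefficients), names prefixed `s<i>_`.
#' @export
extract_array_features <- function(responses, b = NULL,
                                   a_values = c(0.1, 0.01, 0.001),
                                   n_sensors = length(responses)) {
  if (length(responses) == 0L) stop("no sensor responses supplied")
  if (length(responses) != n_sensors)
    stop(sprintf("expected %d sensors, got %d", n_sensors, length(responses)))
  feats <- lapply(seq_along(responses), function(i) {
    f <- extract_sensor_features(responses[[i]], b = b, a_values = a_values)
    names(f) <- paste0("s", i, "_", names(f))
    f
  })
  unlist(feats)
}

#' Read raw transients from a CSV file
#'
#' Expected layout: a time-index column followed by one column per sensor.
#'
#' @param path CSV path.
#' @return List of per-sensor numeric series.
#' @export
read_transients_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected a time column plus at least one sensor column")
  lapply(d[-1], as.numeric)
}
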