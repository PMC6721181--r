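#' Specify a synthetic drifting-batch benchmark
#'
#' Describes class-conditional Gaussian clusters whose means translate
#' over batch time, the drift phenomenology seen in gas-sensor arrays:
#' every batch t draws class k from
#' `N(mu_k + (t - 1) * v_k + jitter_t, sigma^2 I)`. The drift velocity of
#' each class is the sum of a direction shared by all classes (the common
#' sensor-aging component) and a class-specific component, so classes
#' also move relative to each other and a frozen classifier degrades.
#'
#' The defaults mirror the shape of the public gas-sensor drift
#' benchmark: 6 classes, 10 batches, moderate class separation, drift
#' strong enough to pull batch-10 distributions well away from batch 1.
#' `D = 8` keeps simulation studies fast; set `n_dim = 128` for
#' benchmark-sized vectors.
#'
#' @param n_classes K >= 2 (default 6).
#' @param n_dim Feature dimension D (default 8).
#' @param n_batches Number of batches (default 10).
#' @param batch_sizes Integer vector (recycled) of batch sizes (default
#'   150, i.e. 25 per class).
#' @param class_sep Scale of the initial class-mean spread (default 3;
#'   means are drawn from `N(0, class_sep^2)` per coordinate).
#' @param drift_common Per-batch length of the shared drift velocity
#'   (default 1.2).
#' @param drift_class Per-batch length of each class's own velocity
#'   component (default 0.6).
#' @param noise_sd Within-class standard deviation per coordinate
#'   (default 1).
#' @param jitter_sd Standard deviation of the small per-batch mean jitter
#'   (default 0.05).
#' @param imbalance Dirichlet concentration of the per-batch class
#'   proportions; real drift benchmarks show strongly varying class
#'   composition across batches, so the default is 1 (uniform on the
#'   simplex, heavy imbalance). `Inf` gives near-equal class sizes. Every
#'   class keeps at least 2 samples per batch.
#' @param break_last Add a large extra jump (`5 * drift_common`, shared
#'   direction) to the final batch, mimicking a long recording gap before
#'   it (default FALSE).
#' @param seed Master seed fixing means, velocities and samples.
#' @return A list of class `drift_spec`.
#' @export
drift_spec <- function(n_classes = 6L, n_dim = 8L, n_batches = 10L,
                       batch_sizes = 150L, class_sep = 3,
                       drift_common = 1.2, drift_class = 0.6,
                       noise_sd = 1, jitter_sd = 0.05, imbalance = 1,
                       break_last = FALSE, seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  batch_sizes <- rep_len(as.integer(batch_sizes), n_batches)
  if (any(batch_sizes < 2L * n_classes))
    stop("each batch needs >= 2 * n_classes samples")
  if (!(imbalance > 0)) stop("imbalance concentration must be positive")
  structure(list(n_classes = as.integer(n_classes), n_dim = as.integer(n_dim),
                 n_batches = as.integer(n_batches), batch_sizes = batch_sizes,
                 class_sep = class_sep, drift_common = drift_common,
                 drift_class = drift_class, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, imbalance = imbalance,
                 break_last = break_last, seed = as.integer(seed)),
            class = "drift_spec")
}

unit_vector <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

#' Latent structure of a synthetic drift specification
#'
#' Returns the deterministic quantities behind [generate_drift_sequence()]
#' for a given spec: the batch-1 class means, the shared drift direction
#' and the per-class drift velocity vectors. Useful for parameter-recovery
#' checks against generated samples.
#'
#' @param spec A [drift_spec()].
#' @return List with `mu0` (K x D), `common_dir` (unit vector, length D)
#'   and `velocities` (K x D; class k's per-batch mean displacement).
#' @export
drift_structure <- function(spec) {
  K <- spec$n_classes; D <- spec$n_dim
  set.seed(derive_seed(spec$seed, "structure"))
  mu0 <- matrix(stats::rnorm(K * D, sd = spec$class_sep), K, D)
  common_dir <- unit_vector(D)
  vel <- t(vapply(seq_len(K), function(k)
    spec$drift_common * common_dir + spec$drift_class * unit_vector(D),
    numeric(D)))
  list(mu0 = mu0, common_dir = common_dir, velocities = vel)
}

# per-class sample counts for one batch: Dirichlet(imbalance) proportions,
# largest-remainder rounding, floor of 2 per class
class_counts <- function(n, K, imbalance) {
  if (is.infinite(imbalance)) return(diff(round(seq(0, n, length.out = K + 1))))
  g <- stats::rgamma(K, shape = imbalance)
  p <- g / sum(g)
  target <- 2 + p * (n - 2 * K)
  per <- floor(target)
  rem <- n - sum(per)
  if (rem > 0) {
    ord <- order(target - per, decreasing = TRUE)
    per[ord[seq_len(rem)]] <- per[ord[seq_len(rem)]] + 1L
  }
  as.integer(per)
}

#' Generate a synthetic drifting batch sequence
#'
#' Draws the batch sequence described by a [drift_spec()]. Class labels
#' are `"c1" .. "cK"`; samples within each batch are shuffled so class
#' blocks are not contiguous. Deterministic given the spec's seed.
#'
#' @param spec A `drift_spec`.
#' @return A labeled [drift_batch_seq()].
#' @examples
#' seq <- generate_drift_sequence(drift_spec(n_classes = 3, n_batches = 4,
#'                                           batch_sizes = 30, seed = 7))
#' length(seq$batches)
#' @export
generate_drift_sequence <- function(spec) {
  stopifnot(inherits(spec, "drift_spec"))
  K <- spec$n_classes; D <- spec$n_dim
  str <- drift_structure(spec)
  mu0 <- str$mu0
  common_dir <- str$common_dir
  vel <- str$velocities
  classes <- paste0("c", seq_len(K))
  batches <- vector("list", spec$n_batches)
  for (t in seq_len(spec$n_batches)) {
    set.seed(derive_seed(spec$seed, "batch", t))
    n <- spec$batch_sizes[t]
    per <- class_counts(n, K, spec$imbalance)
    jitter <- matrix(stats::rnorm(K * D, sd = spec$jitter_sd), K, D)
    shift <- if (spec$break_last && t == spec$n_batches)
      5 * spec$drift_common else 0
    xs <- list(); ys <- character(0)
    for (k in seq_len(K)) {
      center <- mu0[k, ] + (t - 1) * vel[k, ] + jitter[k, ] +
        shift * common_dir
      xs[[k]] <- matrix(stats::rnorm(per[k] * D, sd = spec$noise_sd),
                        per[k], D, byrow = TRUE) +
        matrix(center, per[k], D, byrow = TRUE)
      ys <- c(ys, rep(classes[k], per[k]))
    }
    x <- do.call(rbind, xs)
    ord <- sample.int(nrow(x))
    batches[[t]] <- drift_batch(x[ord, , drop = FALSE], y = ys[ord],
                                batch_id = t)
  }
  drift_batch_seq(batches, label_set = classes)
}

#' Simulate raw sensor-array transients
#'
#' Produces rise-plateau-decay resistance curves (saturating-exponential
#' rise to a class- and sensor-dependent amplitude, exponential recovery
#' after the injection stops) on a positive baseline, with optional
#' additive noise and a per-sample baseline drift. Feature extraction of
#' these transients with [extract_array_features()] yields linearly
#' separable classes when drift and noise are zero.
#'
#' @param n_per_class Samples per class.
#' @param amplitudes Numeric vector of per-class response amplitudes (its
#'   length sets the class count).
#' @param n_sensors Sensors in the array (default 16).
#' @param len Samples per transient (default 100).
#' @param baseline Baseline resistance (> 0, default 10).
#' @param rise_tau,decay_tau Time constants of the rise and recovery
#'   stages.
#' @param noise_sd Additive measurement noise (default 0).
#' @param baseline_drift Linear per-sample shift added to the baseline
#'   (default 0).
#' @param seed Integer seed.
#' @return A list with `responses` (list over samples; each element a
#'   list of per-sensor numeric series), `labels` (character), and
#'   `boundary` (the 0-based rise/decay boundary index shared by all
#'   curves).
#' @export
generate_transients <- function(n_per_class, amplitudes, n_sensors = 16L,
                                len = 100L, baseline = 10, rise_tau = 8,
                                decay_tau = 15, noise_sd = 0,
                                baseline_drift = 0, seed = 1L) {
  if (baseline <= 0) stop("baseline must be positive")
  K <- length(amplitudes)
  if (K < 1L) stop("need at least one class amplitude")
  b <- floor(len / 2)                      # injection stops mid-recording
  k_idx <- 0:(len - 1)
  set.seed(derive_seed(seed, "transients"))
  responses <- list(); labels <- character(0)
  sensor_gain <- seq(0.5, 1.5, length.out = n_sensors)  # fixed array profile
  s <- 0L
  for (cl in seq_len(K)) {
    for (i in seq_len(n_per_class)) {
      s <- s + 1L
      base_s <- baseline + baseline_drift * (s - 1)
      curves <- lapply(seq_len(n_sensors), function(j) {
        A <- amplitudes[cl] * sensor_gain[j]
        rise <- A * (1 - exp(-k_idx[k_idx <= b] / rise_tau))
        peak <- A * (1 - exp(-b / rise_tau))
        decay <- peak * exp(-(k_idx[k_idx > b] - b) / decay_tau)
        r <- base_s + c(rise, decay)
        if (noise_sd > 0) r <- r + stats::rnorm(len, sd = noise_sd)
        r
      })
      responses[[s]] <- curves
      labels[s] <- paste0("c", cl)
    }
  }
  list(responses = responses, labels = labels, boundary = b)
}
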