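#' Causal exponential read-out kernel
#'
#' The temporal filter of the read-out: `u(tau) = exp(-rate * tau)` for
#' lags `tau = 0, 1, ..., support_length - 1` bins. Each presynaptic spike
#' produces a jump followed by exponential decay, mimicking a postsynaptic
#' current. The support is truncated at `ceiling(5/rate)` bins by default
#' (>= 99.3% of the kernel mass).
#'
#' @param rate decay rate per ms; default `1/20` (20-ms time constant).
#' @param support_length kernel length in bins.
#' @param normalized if `TRUE`, divide by the kernel sum so signals with
#'   different time constants share a common amplitude scale.
#' @return Object of class `"exp_kernel"`: list with `values`, `rate`,
#'   `support_length`, `normalized`, `area` (the unnormalized kernel sum).
#' @examples
#' k <- exp_kernel(1/20)
#' k$values[1]            # 1
#' k$values[21]           # exp(-1)
#' @export
exp_kernel <- function(rate = 1 / 20, support_length = ceiling(5 / rate),
                       normalized = FALSE) {
  if (rate <= 0) stop("`rate` must be positive")
  if (support_length < 1) stop("`support_length` must be >= 1")
  u <- exp(-rate * (seq_len(support_length) - 1))
  area <- sum(u)
  if (normalized) u <- u / area
  structure(list(values = u, rate = rate, support_length = support_length,
                 normalized = normalized, area = area),
            class = "exp_kernel")
}

#' @export
print.exp_kernel <- function(x, ...) {
  cat(sprintf("Exponential kernel: rate %g /ms (tau = %g ms), %d bins%s\n",
              x$rate, 1 / x$rate, x$support_length,
              if (x$normalized) ", normalized to unit area" else ""))
  invisible(x)
}

# Causal FIR filtering of each row of Y (trials x bins) with kernel u,
# zero history before the first bin. FFT-based; returns a matrix like Y.
causal_filter_rows <- function(Y, u) {
  K <- ncol(Y); L <- length(u)
  if (L == 1L) return(Y * u)
  n <- stats::nextn(K + L - 1, 2)
  U <- stats::fft(c(u, rep(0, n - L)))
  X <- stats::mvfft(t(cbind(Y, matrix(0, nrow(Y), n - K))))
  out <- Re(stats::mvfft(X * U, inverse = TRUE)) / n
  t(out[seq_len(K), , drop = FALSE])
}

as_weights <- function(weights) {
  if (inherits(weights, "weight_vector")) weights$weights
  else as.numeric(weights)
}

#' Reconstruct the population signal of a single trial
#'
#' Projects the trial's parallel spike trains onto the vector of decoding
#' weights and convolves with the causal exponential kernel:
#' `x(t_k) = sum_tau (w . o(t_{k-tau})) u(tau)`, with zero history before
#' the window. This is the modeled synaptic input current of a read-out
#' neuron, in real time and in a single trial.
#'
#' @param spikes_trial binary neuron x bin matrix for one trial.
#' @param weights a `"weight_vector"` or numeric vector, one per neuron.
#' @param kernel an [exp_kernel()].
#' @return Numeric vector of length `K` (the signal per time bin).
#' @export
reconstruct_trial <- function(spikes_trial, weights, kernel = exp_kernel()) {
  w <- as_weights(weights)
  if (!is.matrix(spikes_trial)) stop("`spikes_trial` must be a matrix")
  if (length(w) != nrow(spikes_trial))
    stop("weight length must equal the neuron count")
  y <- drop(w %*% spikes_trial)
  drop(causal_filter_rows(matrix(y, 1L), kernel$values))
}

#' Reconstruct population signals for many trials
#'
#' Vectorized form of [reconstruct_trial()] over the trials of a spike
#' train set.
#'
#' @param x a [spike_train_set()] or a neuron x trial x bin array.
#' @param weights weights as in [reconstruct_trial()].
#' @param kernel an [exp_kernel()].
#' @param trials trial indices to reconstruct (default all).
#' @return Trials x bins matrix of population signals.
#' @export
reconstruct_trials <- function(x, weights, kernel = exp_kernel(),
                               trials = NULL) {
  spk <- if (inherits(x, "spike_train_set")) x$spikes else x
  w <- as_weights(weights)
  d <- dim(spk)
  if (length(w) != d[1L]) stop("weight length must equal the neuron count")
  if (is.null(trials)) trials <- seq_len(d[2L])
  spk <- spk[, trials, , drop = FALSE]
  Y <- matrix(w, 1L, d[1L]) %*% matrix(spk, d[1L])
  Y <- matrix(Y, length(trials), d[3L])
  causal_filter_rows(Y, kernel$values)
}

# Per-neuron convolved spike trains for a set of trials: returns an
# N x length(trials) x K array. Signals for any weight vector are then a
# single tensor contraction, which makes permutation nulls cheap.
convolved_spikes <- function(x, kernel = exp_kernel(), trials = NULL) {
  spk <- if (inherits(x, "spike_train_set")) x$spikes else x
  d <- dim(spk)
  if (is.null(trials)) trials <- seq_len(d[2L])
  spk <- spk[, trials, , drop = FALSE]
  nj <- d[1L] * length(trials)
  R <- causal_filter_rows(matrix(spk, nj, d[3L]), kernel$values)
  array(R, dim = c(d[1L], length(trials), d[3L]))
}

# Contract a precomputed convolved-spikes array with a weight vector.
contract_weights <- function(R, weights) {
  w <- as_weights(weights)
  d <- dim(R)
  matrix(matrix(w, 1L, d[1L]) %*% matrix(R, d[1L]), d[2L], d[3L])
}

#' Center per-trial signals and average by condition
#'
#' Subtracts the across-trial mean signal `z(t_k)` from every trial,
#' averages the centered signals within each condition, and forms the
#' difference statistic `match - non-match` that quantifies single-trial
#' discriminability bin by bin.
#'
#' @param per_trial trials x bins matrix of population signals.
#' @param labels class vector in `{-1, +1}` aligned with the rows.
#' @param group optional tag for which (sub)population produced the signal.
#' @param time optional bin times in ms.
#' @return Object of class `"population_signal"`: `per_trial`, `centered`,
#'   `mean_all`, `cond_mean_match`, `cond_mean_nonmatch`, `difference`,
#'   `labels`, `group`, `time`, `valid`.
#' @export
center_and_average <- function(per_trial, labels, group = "all", time = NULL) {
  labels <- as.integer(labels)
  if (nrow(per_trial) != length(labels)) stop("labels/trials mismatch")
  if (!all(c(-1L, 1L) %in% labels)) stop("both conditions must be present")
  z <- colMeans(per_trial)
  centered <- sweep(per_trial, 2L, z)
  m <- colMeans(centered[labels == 1L, , drop = FALSE])
  nm <- colMeans(centered[labels == -1L, , drop = FALSE])
  structure(list(per_trial = per_trial, centered = centered, mean_all = z,
                 cond_mean_match = m, cond_mean_nonmatch = nm,
                 difference = m - nm, labels = labels, group = group,
                 time = if (is.null(time)) seq_len(ncol(per_trial)) - 1 else time,
                 valid = TRUE),
            class = "population_signal")
}

#' @export
print.population_signal <- function(x, ...) {
  cat(sprintf(
    "Population signal [%s]: %d trials x %d bins%s; mean |match - nonmatch| = %.4g\n",
    x$group, nrow(x$per_trial), ncol(x$per_trial),
    if (!isTRUE(x$valid)) " (INVALID)" else "",
    mean(abs(x$difference))))
  invisible(x)
}

zero_population_signal <- function(n_trials, n_bins, labels, group) {
  out <- structure(list(per_trial = matrix(0, n_trials, n_bins),
                        centered = matrix(0, n_trials, n_bins),
                        mean_all = numeric(n_bins),
                        cond_mean_match = numeric(n_bins),
                        cond_mean_nonmatch = numeric(n_bins),
                        difference = numeric(n_bins),
                        labels = as.integer(labels), group = group,
                        time = seq_len(n_bins) - 1, valid = FALSE),
                   class = "population_signal")
  out
}

new_subpop_spec <- function(mask, kind, g) {
  n_sub <- sum(mask)
  structure(list(mask = mask, kind = kind, n_sub = n_sub,
                 correction = if (n_sub > 0) length(mask) / (g * n_sub) else NA_real_,
                 valid = n_sub > 0),
            class = "subpop_spec")
}

#' @export
print.subpop_spec <- function(x, ...) {
  cat(sprintf("Subpopulation [%s]: %d/%d neurons, correction factor %s%s\n",
              x$kind, x$n_sub, length(x$mask),
              format(x$correction, digits = 4),
              if (!x$valid) " (INVALID: empty)" else ""))
  invisible(x)
}

#' Split neurons by the sign of their decoding weight
#'
#' Partitions the population into "plus" neurons (weight > 0) and "minus"
#' neurons (weight < 0); zero-weight neurons belong to neither pool. Each
#' pool carries the size-correction factor `f = N / (2 * N_pool)` so that
#' pool signals are on a scale comparable to the full-population signal.
#'
#' @param weights a `"weight_vector"` or numeric vector.
#' @return List with elements `plus` and `minus`, each a `"subpop_spec"`
#'   (mask, pool size `n_sub`, `correction`, validity flag). An empty pool
#'   yields an invalid spec.
#' @export
sign_split <- function(weights) {
  w <- as_weights(weights)
  list(plus = new_subpop_spec(w > 0, "plus", g = 2),
       minus = new_subpop_spec(w < 0, "minus", g = 2))
}

#' Split neurons by cortical layer
#'
#' Builds one masked-weight specification per layer (SG, G, IG) with
#' size-correction factor `f_r = N / (3 * N_r)`.
#'
#' @param weights a `"weight_vector"` or numeric vector.
#' @param layers per-neuron layer tags (`"SG"`, `"G"`, `"IG"`) or a
#'   `"layer_assignment"` carrying `neuron_layers`.
#' @return Named list of three `"subpop_spec"`s; empty layers are flagged
#'   invalid.
#' @export
layer_split <- function(weights, layers) {
  w <- as_weights(weights)
  if (inherits(layers, "layer_assignment")) layers <- layers$neuron_layers
  layers <- as.character(layers)
  if (length(layers) != length(w)) stop("one layer tag per neuron required")
  if (!all(layers %in% c("SG", "G", "IG")))
    stop("layers must be 'SG', 'G' or 'IG'")
  stats::setNames(lapply(c("SG", "G", "IG"), function(r)
    new_subpop_spec(layers == r, r, g = 3)), c("SG", "G", "IG"))
}

#' Subpopulation population signal
#'
#' Reconstructs the population signal using only the neurons selected by a
#' subpopulation spec: off-mask weights are set to zero and on-mask weights
#' are scaled by the pool's size-correction factor before the spike
#' projection. The signal is centered with the subpopulation's own
#' across-trial mean and condition-averaged.
#'
#' @param x a [spike_train_set()] or neuron x trial x bin array.
#' @param weights full-population weights.
#' @param spec a `"subpop_spec"` from [sign_split()] or [layer_split()].
#' @param kernel an [exp_kernel()].
#' @param labels class labels for the reconstructed trials; defaults to the
#'   set's labels (subset by `trials`).
#' @param trials trial indices (e.g. a validation set); default all.
#' @return A `"population_signal"` with `group = spec$kind`; if the spec is
#'   invalid (empty pool) an all-zero signal flagged `valid = FALSE`.
#' @export
subpop_signal <- function(x, weights, spec, kernel = exp_kernel(),
                          labels = NULL, trials = NULL) {
  stopifnot(inherits(spec, "subpop_spec"))
  spk <- if (inherits(x, "spike_train_set")) x$spikes else x
  d <- dim(spk)
  if (is.null(trials)) trials <- seq_len(d[2L])
  if (is.null(labels)) {
    if (!inherits(x, "spike_train_set"))
      stop("`labels` required when `x` is a bare array")
    labels <- x$labels[trials]
  }
  if (!spec$valid) {
    warning(sprintf("empty subpopulation '%s'; returning all-zero signal",
                    spec$kind))
    return(zero_population_signal(length(trials), d[3L], labels, spec$kind))
  }
  w <- as_weights(weights)
  w_sub <- ifelse(spec$mask, w, 0) * spec$correction
  per_trial <- reconstruct_trials(spk, w_sub, kernel, trials)
  center_and_average(per_trial, labels, group = spec$kind)
}

#' Single-neuron population signals from univariate AUC weights
#'
#' For each neuron independently, weights its spike train by its univariate
#' AUC-based decoding weight, filters with the exponential kernel, centers
#' across trials and averages by condition. Each neuron's signal depends
#' only on its own spikes.
#'
#' @param x a [spike_train_set()].
#' @param aucw a `"weight_vector"` with `method = "auc"`.
#' @param kernel an [exp_kernel()].
#' @param labels,trials as in [subpop_signal()].
#' @return List of `"population_signal"` objects, one per neuron
#'   (`group = "neuron:<id>"`).
#' @export
univariate_signals <- function(x, aucw, kernel = exp_kernel(),
                               labels = NULL, trials = NULL) {
  stopifnot(inherits(x, "spike_train_set"))
  if (!identical(aucw$method, "auc"))
    stop("`aucw` must be AUC-based weights (method 'auc')")
  if (is.null(trials)) trials <- seq_len(x$n_trials)
  if (is.null(labels)) labels <- x$labels[trials]
  w <- aucw$weights
  lapply(seq_len(x$n_neurons), function(n) {
    Y <- w[n] * matrix(x$spikes[n, trials, , drop = FALSE],
                       length(trials), x$n_bins)
    per_trial <- causal_filter_rows(Y, kernel$values)
    center_and_average(per_trial, labels,
                       group = paste0("neuron:", x$neuron_ids[n]))
  })
}

#' Write population signals as delimited text
#'
#' Long format, tab-separated: session, group, condition, time_ms, value,
#' with one row per time bin for the two condition means and their
#' difference.
#'
#' @param signal a `"population_signal"`.
#' @param path output file path.
#' @param session_id session identifier.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path, session_id = "session") {
  df <- data.frame(
    session = session_id, group = signal$group,
    condition = rep(c("match", "nonmatch", "difference"),
                    each = length(signal$time)),
    time_ms = rep(signal$time, 3L),
    value = c(signal$cond_mean_match, signal$cond_mean_nonmatch,
              signal$difference))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
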