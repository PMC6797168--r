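#' Construct a set of parallel spike trains
#'
#' Bundles simultaneously recorded binary spike trains with their trial
#' labels into the container used throughout the package. Spike trains are
#' stored as a 3-dimensional array indexed (neuron, trial, time bin), with
#' 1-ms bins by default; every entry must be 0 or 1. Trial labels encode the
#' two task conditions: `+1` for "match" and `-1` for "non-match".
#'
#' @param spikes numeric array of dimension `N x J x K` (neurons x trials x
#'   time bins) containing only 0s and 1s.
#' @param labels integer vector of length `J` with values in `{-1, +1}`;
#'   both classes must be present.
#' @param bin_width bin width in ms (default 1).
#' @param window_start time of the first bin relative to stimulus onset, ms.
#' @param epoch which task epoch the window covers: `"test"` or `"target"`.
#' @param neuron_ids optional identifiers, one per neuron.
#' @param session_id session identifier string.
#' @param depths optional per-neuron recording depth along the laminar probe
#'   (same units as the probe's channel spacing), used for layer assignment.
#' @return An object of class `"spike_train_set"`: a list with the validated
#'   fields above plus `n_neurons`, `n_trials`, `n_bins`.
#' @examples
#' spk <- array(rbinom(2 * 4 * 50, 1, 0.05), dim = c(2, 4, 50))
#' sts <- spike_train_set(spk, labels = c(-1, -1, 1, 1))
#' sts$n_bins
#' @export
spike_train_set <- function(spikes, labels, bin_width = 1, window_start = 0,
                            epoch = c("test", "target"), neuron_ids = NULL,
                            session_id = "session", depths = NULL) {
  epoch <- match.arg(epoch)
  if (!is.array(spikes) || length(dim(spikes)) != 3L)
    stop("`spikes` must be a 3-d array (neuron x trial x time bin)")
  if (length(spikes) == 0L) stop("no data")
  if (!all(spikes %in% c(0, 1))) stop("`spikes` entries must be 0 or 1")
  storage.mode(spikes) <- "integer"
  d <- dim(spikes)
  labels <- as.integer(labels)
  if (length(labels) != d[2L])
    stop("`labels` length must equal the trial dimension of `spikes`")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  if (!all(c(-1L, 1L) %in% labels))
    stop("both classes (-1 and +1) must be present")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(d[1L]))
  if (!is.null(depths) && length(depths) != d[1L])
    stop("`depths` must have one entry per neuron")
  structure(list(
    spikes = spikes, labels = labels, bin_width = bin_width,
    window_start = window_start, epoch = epoch,
    neuron_ids = as.character(neuron_ids), session_id = session_id,
    depths = depths,
    n_neurons = d[1L], n_trials = d[2L], n_bins = d[3L]
  ), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "Spike train set '%s' (%s epoch): %d neurons, %d trials, %d bins of %g ms\n",
    x$session_id, x$epoch, x$n_neurons, x$n_trials, x$n_bins, x$bin_width))
  cat(sprintf("  trials: %d match, %d non-match; window starts at %g ms\n",
              sum(x$labels == 1L), sum(x$labels == -1L), x$window_start))
  invisible(x)
}

#' Time axis of a spike train set
#'
#' @param x a `spike_train_set`.
#' @return Numeric vector of bin start times in ms (relative to stimulus
#'   onset), length `n_bins`.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "spike_train_set"))
  x$window_start + (seq_len(x$n_bins) - 1) * x$bin_width
}

# Map a half-open time window [from, to) in ms to bin indices.
window_bins <- function(x, window) {
  tt <- time_axis(x)
  idx <- which(tt >= window[1] & tt < window[2])
  if (length(idx) == 0L) stop("window contains no recorded bins")
  idx
}

#' Population peristimulus time histogram with Gaussian smoothing
#'
#' Averages spike trains across neurons and across trials, bin by bin, and
#' smooths the result with a Gaussian kernel normalized to unit sum over its
#' finite support. With 0/1 spikes the raw series is the per-bin spike
#' probability of an average neuron; the smoothed series stays in \[0, 1\]
#' up to edge attenuation from zero-padding.
#'
#' @param x a [spike_train_set()].
#' @param sigma_sq variance of the Gaussian kernel in ms^2 (default 10).
#' @param support_halfwidth half-width of the kernel support in ms (default
#'   10, giving support -10..10 ms); must be at least one kernel SD.
#' @return Object of class `"smoothed_psth"`: list with `values` (smoothed
#'   series), `raw` (unsmoothed average), `kernel` (weights summing to 1),
#'   `support` (lag values in ms), `time` (bin times).
#' @examples
#' spk <- array(0L, dim = c(2, 2, 40)); spk[1, 1, 20] <- 1L
#' p <- population_psth(spike_train_set(spk, c(-1, 1)))
#' sum(p$values)  # 1/(N*J) = 0.25, mass preserved away from edges
#' @export
population_psth <- function(x, sigma_sq = 10, support_halfwidth = 10) {
  stopifnot(inherits(x, "spike_train_set"))
  if (sigma_sq <= 0) stop("`sigma_sq` must be positive")
  if (support_halfwidth < sqrt(sigma_sq))
    stop("`support_halfwidth` must be at least one kernel SD")
  raw <- apply(x$spikes, 3L, mean)
  tau <- seq.int(-support_halfwidth, support_halfwidth)
  w <- exp(-tau^2 / (2 * sigma_sq))
  w <- w / sum(w)
  h <- support_halfwidth
  padded <- c(rep(0, h), raw, rep(0, h))
  K <- length(raw)
  vals <- vapply(seq_len(K), function(k) sum(w * padded[k - tau + h]), 0.0)
  structure(list(values = vals, raw = raw, kernel = w, support = tau,
                 sigma_sq = sigma_sq, time = time_axis(x)),
            class = "smoothed_psth")
}

#' @export
print.smoothed_psth <- function(x, ...) {
  cat(sprintf("Smoothed population PSTH: %d bins, kernel variance %g ms^2\n",
              length(x$values), x$sigma_sq))
  invisible(x)
}

#' Spike counts and z-scored counts over a time window
#'
#' Sums spikes per neuron and trial over a half-open window and z-scores the
#' counts per neuron: the deviation of the count from its mean across trials
#' in units of its standard deviation. The mean and variance are estimated
#' on `stats_trials` only (by default, all trials) and then applied to every
#' trial, so statistics can be estimated on training trials and applied to
#' held-out trials without leakage.
#'
#' @param x a [spike_train_set()].
#' @param window numeric length-2, half-open window `[from, to)` in ms;
#'   default the full recorded window.
#' @param stats_trials trial indices used to estimate the per-neuron mean
#'   and variance (default all trials).
#' @param ddof degrees-of-freedom correction for the variance: 1 (default)
#'   gives the sample variance, 0 the population variance.
#' @return Object of class `"count_matrix"`: list with `counts` and
#'   `zscores` (both neuron x trial), `window`, and `zscore_stats` (per
#'   neuron mean, variance, the trials used, and `ddof`). Neurons with zero
#'   variance over `stats_trials` get all-zero z-scores with a warning.
#' @examples
#' spk <- array(0L, dim = c(1, 3, 10))
#' spk[1, 2, 1:2] <- 1L; spk[1, 3, 1:4] <- 1L  # counts 0, 2, 4
#' cm <- spike_counts_zscored(spike_train_set(spk, c(-1, 1, 1)))
#' cm$zscores
#' @export
spike_counts_zscored <- function(x, window = NULL, stats_trials = NULL,
                                 ddof = 1) {
  stopifnot(inherits(x, "spike_train_set"))
  if (is.null(window))
    window <- c(x$window_start, x$window_start + x$n_bins * x$bin_width)
  bins <- window_bins(x, window)
  if (is.null(stats_trials)) stats_trials <- seq_len(x$n_trials)
  if (length(stats_trials) == 0L) stop("`stats_trials` must be non-empty")
  counts <- rowSums(x$spikes[, , bins, drop = FALSE], dims = 2L)
  dim(counts) <- c(x$n_neurons, x$n_trials)
  sub <- counts[, stats_trials, drop = FALSE]
  m <- rowMeans(sub)
  n <- ncol(sub)
  v <- rowSums((sub - m)^2) / max(n - ddof, 1)
  z <- (counts - m) / sqrt(v)
  zero_var <- v == 0
  if (any(zero_var)) {
    z[zero_var, ] <- 0
    warning(sprintf("%d neuron(s) with zero count variance; z-scores set to 0",
                    sum(zero_var)))
  }
  structure(list(counts = counts, zscores = z, window = window,
                 zscore_stats = list(mean = m, var = v,
                                     trials = stats_trials, ddof = ddof)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d neurons x %d trials, window [%g, %g) ms\n",
              nrow(x$counts), ncol(x$counts), x$window[1], x$window[2]))
  invisible(x)
}

# Resolve a weights/zscores argument pair used by several learners.
as_count_matrix_input <- function(x, what = c("zscores", "counts")) {
  what <- match.arg(what)
  if (inherits(x, "count_matrix")) x[[what]]
  else if (is.matrix(x)) x
  else stop("expected a `count_matrix` or a neuron x trial matrix")
}
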