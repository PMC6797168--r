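new_ccf_result <- function(lags, values, pair, condition, valid = TRUE,
                           per_trial = NULL, n_trials = NA_integer_,
                           n_dropped = 0L) {
  structure(list(lags = lags, values = values, pair = pair,
                 condition = condition, valid = valid, per_trial = per_trial,
                 n_trials = n_trials, n_dropped = n_dropped),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  lag0 <- x$values[x$lags == 0]
  cat(sprintf("CCF [%s, %s]: lags %d..%d, value at lag 0 = %s%s\n",
              x$pair, x$condition, min(x$lags), max(x$lags),
              format(lag0, digits = 4),
              if (!x$valid) " (INVALID: zero-energy signal)" else ""))
  invisible(x)
}

# Full linear cross-correlation r(tau) = sum_k x[k] y[k+tau] over
# tau = -(K-1)..(K-1), FFT-based.
raw_ccf <- function(x, y) {
  stats::convolve(y, x, type = "open")  # index K + tau
}

#' Normalized cross-correlation of two single-trial signals
#'
#' Raw lagged products `R_xy(tau) = sum_k x(t_k) y(t_{k+tau})` for
#' `tau >= 0`, extended to negative lags by `R_xy(-tau) = R_yx(tau)`, and
#' normalized by the geometric mean of the two zero-lag autocorrelations,
#' `sqrt(R_xx(0) R_yy(0))`. By the Cauchy-Schwarz inequality the
#' normalized values lie in `[-1, 1]`, with the self-correlation equal to
#' 1 at lag 0.
#'
#' @param x,y numeric series of equal length `K >= 2`.
#' @param pair label for the signal pair.
#' @param condition label for the trial condition.
#' @return A `"ccf_result"` with `lags` `-(K-1)..(K-1)` (in bins) and
#'   `values`. If either signal is identically zero the normalization is
#'   undefined: values are `NA` and the result is flagged invalid.
#' @export
ccf_single_trial <- function(x, y, pair = "x:y", condition = "both") {
  if (length(x) != length(y)) stop("signals must have equal length")
  K <- length(x)
  if (K < 2L) stop("signals must have length >= 2")
  lags <- seq.int(-(K - 1L), K - 1L)
  e_x <- sum(x^2); e_y <- sum(y^2)
  if (e_x == 0 || e_y == 0)
    return(new_ccf_result(lags, rep(NA_real_, 2L * K - 1L), pair, condition,
                          valid = FALSE, n_trials = 1L))
  new_ccf_result(lags, raw_ccf(x, y) / sqrt(e_x * e_y), pair, condition,
                 n_trials = 1L)
}

#' Trial-averaged normalized cross-correlation
#'
#' Computes the normalized cross-correlation function in every trial
#' (pairing row `j` of `signals_a` with row `j` of `signals_b`, two
#' simultaneous population signals from the same trial) and averages
#' across trials of the requested condition, or across all trials.
#' Trials where either signal has zero energy are dropped from the
#' average; the dropped count is reported.
#'
#' @param signals_a,signals_b trials x bins matrices of aligned signals
#'   (e.g. `$per_trial` of two [subpop_signal()] results).
#' @param labels class vector in `{-1, +1}` aligned with the rows.
#' @param condition `"both"` (default), `"match"` or `"nonmatch"`.
#' @param pair label for the signal pair.
#' @param keep_per_trial if `TRUE`, retain the per-trial CCF matrix.
#' @param mean_subtract if `TRUE`, subtract each trial's time-mean from both
#'   signals before correlating (a Pearson-style variant); the default uses
#'   the signals exactly as produced by the reconstruction.
#' @return A `"ccf_result"` with the averaged `values`, `n_trials` used and
#'   `n_dropped`.
#' @export
ccf_trial_averaged <- function(signals_a, signals_b, labels,
                               condition = c("both", "match", "nonmatch"),
                               pair = "a:b", keep_per_trial = FALSE,
                               mean_subtract = FALSE) {
  if (mean_subtract) {
    signals_a <- signals_a - rowMeans(signals_a)
    signals_b <- signals_b - rowMeans(signals_b)
  }
  condition <- match.arg(condition)
  labels <- as.integer(labels)
  if (nrow(signals_a) != nrow(signals_b) ||
      ncol(signals_a) != ncol(signals_b)) stop("signal matrices must align")
  if (nrow(signals_a) != length(labels)) stop("labels/trials mismatch")
  keep <- switch(condition, both = rep(TRUE, length(labels)),
                 match = labels == 1L, nonmatch = labels == -1L)
  if (!any(keep)) stop(sprintf("no trials in condition '%s'", condition))
  idx <- which(keep)
  K <- ncol(signals_a)
  per <- matrix(NA_real_, length(idx), 2L * K - 1L)
  ok <- logical(length(idx))
  for (i in seq_along(idx)) {
    j <- idx[i]
    r <- ccf_single_trial(signals_a[j, ], signals_b[j, ], pair, condition)
    ok[i] <- r$valid
    if (r$valid) per[i, ] <- r$values
  }
  if (!any(ok)) {
    return(new_ccf_result(seq.int(-(K - 1L), K - 1L),
                          rep(NA_real_, 2L * K - 1L), pair, condition,
                          valid = FALSE, n_trials = 0L,
                          n_dropped = sum(!ok)))
  }
  vals <- colMeans(per[ok, , drop = FALSE])
  new_ccf_result(seq.int(-(K - 1L), K - 1L), vals, pair, condition,
                 per_trial = if (keep_per_trial) per[ok, , drop = FALSE],
                 n_trials = sum(ok), n_dropped = sum(!ok))
}

#' Random-assignment null for subpopulation cross-correlations
#'
#' Null distribution of the trial-averaged plus/minus (or layer-pair)
#' cross-correlation when the assignment of neurons to subpopulations is
#' randomized: in each replicate the weight vector (for `"pool"`) or the
#' layer tags (for `"layer"`) are permuted across neurons, preserving pool
#' and layer sizes and the set of weight values, and the two
#' subpopulation signals and their averaged CCF are recomputed.
#'
#' @param x a [spike_train_set()].
#' @param weights the learned weights.
#' @param what `"pool"` (plus x minus) or `"layer"`.
#' @param pair for `what = "layer"`, a length-2 character vector naming the
#'   layer pair, e.g. `c("SG", "G")`.
#' @param layers per-neuron layer tags (required for `what = "layer"`).
#' @param trials,labels trials to use and their labels (default all).
#' @param kernel an [exp_kernel()].
#' @param nperm replicates.
#' @param seed RNG seed.
#' @param mean_subtract passed to [ccf_trial_averaged()]; use the same
#'   setting as for the observed CCF.
#' @return A `"null_ensemble"` with `nperm` rows over the `2K - 1` lags,
#'   `mode = "random_pool_assignment"` or `"random_layer_assignment"`.
#' @export
assignment_ccf_null <- function(x, weights, what = c("pool", "layer"),
                                pair = c("SG", "G"), layers = NULL,
                                trials = NULL, labels = NULL,
                                kernel = exp_kernel(), nperm = 1000,
                                seed = 1, mean_subtract = FALSE) {
  what <- match.arg(what)
  stopifnot(inherits(x, "spike_train_set"))
  if (is.null(trials)) trials <- seq_len(x$n_trials)
  if (is.null(labels)) labels <- x$labels[trials]
  w <- as_weights(weights)
  N <- length(w)
  R <- convolved_spikes(x, kernel, trials = trials)
  one_rep <- function() {
    p <- sample(N)
    if (what == "pool") {
      ss <- sign_split(w[p])
      sa <- ss$plus; sb <- ss$minus
      wp <- w[p]
    } else {
      lp <- layers[p]
      ls <- layer_split(w, lp)
      sa <- ls[[pair[1]]]; sb <- ls[[pair[2]]]
      wp <- w
    }
    if (!sa$valid || !sb$valid) return(rep(NA_real_, 2L * x$n_bins - 1L))
    A <- contract_weights(R, ifelse(sa$mask, wp, 0) * sa$correction)
    B <- contract_weights(R, ifelse(sb$mask, wp, 0) * sb$correction)
    ccf_trial_averaged(A, B, labels, "both",
                       mean_subtract = mean_subtract)$values
  }
  samples <- with_seed(seed,
    t(vapply(seq_len(nperm), function(r) one_rep(),
             numeric(2L * x$n_bins - 1L))))
  mode <- if (what == "pool") "random_pool_assignment"
          else "random_layer_assignment"
  new_null_ensemble(samples, mode, seed,
                    axis = seq.int(-(x$n_bins - 1L), x$n_bins - 1L))
}

#' Write a cross-correlation function as delimited text
#'
#' Tab-separated columns: pair, condition, lag_ms, value, n_trials. The lag
#' range can be cropped for readability.
#'
#' @param ccf a `"ccf_result"`.
#' @param path output file path.
#' @param bin_width bin width in ms used to convert lags.
#' @param max_lag_ms crop to `|lag| <= max_lag_ms` (default 200; `Inf` for
#'   the full range).
#' @return `path`, invisibly.
#' @export
write_ccf <- function(ccf, path, bin_width = 1, max_lag_ms = 200) {
  lag_ms <- ccf$lags * bin_width
  keep <- abs(lag_ms) <= max_lag_ms
  df <- data.frame(pair = ccf$pair, condition = ccf$condition,
                   lag_ms = lag_ms[keep], value = ccf$values[keep],
                   n_trials = ccf$n_trials)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
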