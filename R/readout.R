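#' Fit the population read-out model
#'
#' The central estimator of the package. Over repeated Monte-Carlo
#' cross-validation splits, the model (i) z-scores the per-neuron spike
#' counts of the training trials, (ii) learns L2-normalized decoding
#' weights with a soft-margin linear SVM (regularization chosen once per
#' session by nested 5-fold cross-validation on the first training set),
#' (iii) reconstructs the single-trial population signal of the held-out
#' trials by weighting spikes and filtering with a causal exponential
#' kernel, and (iv) centers and condition-averages the signal. Reported
#' weights, balanced accuracies and signal curves are averages across the
#' cross-validation runs.
#'
#' @param x a [spike_train_set()].
#' @param n_cv number of Monte-Carlo cross-validation runs (default 100).
#' @param C fixed SVM regularization; `NULL` (default) selects it from
#'   `C_grid` by 5-fold cross-validation on the first training set.
#' @param C_grid candidate grid for the selection, see [default_C_grid()].
#' @param kernel read-out kernel, see [exp_kernel()].
#' @param window spike-counting window `[from, to)` in ms (default the
#'   full recorded window).
#' @param zscore_scope `"train"` (default) or `"all"`: which trials supply
#'   the z-scoring statistics.
#' @param ddof variance convention for the z-scoring (default 1).
#' @param seed seed controlling splits and the nested fold shuffling.
#' @return Object of class `"readout"` with, among others:
#'   `weights` (per-neuron decoding weights averaged across runs),
#'   `weights_runs` (runs x neurons), `bac` (per-run validation balanced
#'   accuracy), `C`, `signal` (run-averaged condition means and the
#'   `match - non-match` difference), `splits`, `kernel`.
#' @seealso [coef.readout()], [predict.readout()], [plot.readout()],
#'   [run_full_analysis()] for the surrounding survey analyses.
#' @export
readout <- function(x, n_cv = 100, C = NULL, C_grid = default_C_grid(),
                    kernel = exp_kernel(), window = NULL,
                    zscore_scope = c("train", "all"), ddof = 1, seed = 1) {
  stopifnot(inherits(x, "spike_train_set"))
  zscore_scope <- match.arg(zscore_scope)
  splits <- monte_carlo_splits(x$labels, n_runs = n_cv, seed = seed)
  R_all <- convolved_spikes(x, kernel)
  N <- x$n_neurons; K <- x$n_bins
  weights_runs <- matrix(NA_real_, n_cv, N)
  offsets <- numeric(n_cv); bac <- numeric(n_cv)
  diff_acc <- numeric(K); m_acc <- numeric(K); nm_acc <- numeric(K)
  C_scores <- NULL
  for (r in seq_len(n_cv)) {
    sp <- splits[[r]]
    stats_trials <- if (zscore_scope == "train") sp$train else NULL
    cm <- spike_counts_zscored(x, window, stats_trials = stats_trials,
                               ddof = ddof)
    if (is.null(C)) {
      C <- select_regularization(cm$zscores[, sp$train, drop = FALSE],
                                 x$labels[sp$train], grid = C_grid,
                                 seed = seed)
      C_scores <- attr(C, "scores")
      C <- as.numeric(C)
    }
    wv <- learn_weights(cm$zscores[, sp$train, drop = FALSE],
                        x$labels[sp$train], C)
    weights_runs[r, ] <- wv$weights
    offsets[r] <- wv$offset_norm
    f <- drop(wv$weights %*% cm$zscores[, sp$valid, drop = FALSE]) +
      wv$offset_norm
    bac[r] <- balanced_accuracy(ifelse(f > 0, 1L, -1L), x$labels[sp$valid])
    sig <- contract_weights(R_all[, sp$valid, , drop = FALSE], wv$weights)
    ps <- center_and_average(sig, x$labels[sp$valid], time = time_axis(x))
    diff_acc <- diff_acc + ps$difference
    m_acc <- m_acc + ps$cond_mean_match
    nm_acc <- nm_acc + ps$cond_mean_nonmatch
  }
  cm_all <- spike_counts_zscored(x, window, ddof = ddof)
  structure(list(
    weights = colMeans(weights_runs),
    weights_runs = weights_runs, offsets = offsets, bac = bac, C = C,
    C_scores = C_scores,
    signal = list(difference = diff_acc / n_cv,
                  cond_mean_match = m_acc / n_cv,
                  cond_mean_nonmatch = nm_acc / n_cv,
                  time = time_axis(x)),
    splits = splits, kernel = kernel, window = cm_all$window,
    zscore_scope = zscore_scope, ddof = ddof, seed = seed,
    zscore_stats = cm_all$zscore_stats,
    labels = x$labels, n_neurons = N, n_bins = K,
    session_id = x$session_id, epoch = x$epoch,
    neuron_ids = x$neuron_ids,
    call = match.call()
  ), class = "readout")
}

#' @export
print.readout <- function(x, ...) {
  cat(sprintf("Population read-out model: session '%s' (%s epoch)\n",
              x$session_id, x$epoch))
  cat(sprintf("  %d neurons, %d CV runs, C = %g\n",
              x$n_neurons, length(x$bac), x$C))
  cat(sprintf("  validation balanced accuracy: %.3f (SD %.3f)\n",
              mean(x$bac), stats::sd(x$bac)))
  cat(sprintf("  plus/minus neurons (mean weights): %d / %d\n",
              sum(x$weights > 0), sum(x$weights < 0)))
  invisible(x)
}

#' @export
summary.readout <- function(object, ...) {
  structure(list(fit = object,
                 weight_table = data.frame(
                   neuron_id = object$neuron_ids,
                   weight = object$weights,
                   sign = sign(object$weights),
                   sd_across_runs = apply(object$weights_runs, 2L,
                                          stats::sd))),
            class = "summary.readout")
}

#' @export
print.summary.readout <- function(x, ...) {
  print(x$fit)
  d <- x$fit$signal$difference
  cat(sprintf("  time-averaged |match - nonmatch| signal: %.4g\n",
              mean(abs(d))))
  cat("\nPer-neuron decoding weights (averaged across CV runs):\n")
  print(x$weight_table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @describeIn readout per-neuron decoding weights averaged across CV runs.
#' @param object,... a fitted `"readout"` model (further arguments ignored).
#' @export
coef.readout <- function(object, ...) {
  stats::setNames(object$weights, object$neuron_ids)
}

#' Predict condition labels with a fitted read-out model
#'
#' Classifies trials by the sign of the decision value
#' `w . s_z + b`, where `w` are the run-averaged normalized weights, `b`
#' the run-averaged (normalized) offset, and `s_z` the trials' spike
#' counts z-scored with the fitted session's statistics.
#'
#' @param object a fitted `"readout"`.
#' @param newdata a [spike_train_set()] with the same neurons, or a
#'   neuron x trial count matrix; default: the training session's counts.
#' @param type `"class"` for labels in `{-1, +1}`, `"decision"` for the
#'   raw decision values.
#' @param ... ignored.
#' @return Integer class vector or numeric decision values, one per trial.
#' @export
predict.readout <- function(object, newdata = NULL,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  counts <- if (is.null(newdata)) {
    NULL
  } else if (inherits(newdata, "spike_train_set")) {
    spike_counts_zscored(newdata, object$window, ddof = object$ddof)$counts
  } else as_count_matrix_input(newdata, "counts")
  st <- object$zscore_stats
  if (is.null(counts)) stop("`newdata` is required")
  if (nrow(counts) != object$n_neurons) stop("neuron count mismatch")
  z <- (counts - st$mean) / sqrt(st$var)
  z[st$var == 0, ] <- 0
  f <- drop(object$weights %*% z) + mean(object$offsets)
  if (type == "decision") f else ifelse(f > 0, 1L, -1L)
}

#' Plot a fitted read-out model
#'
#' Two base-graphics panels: the run-averaged centered population signal
#' in the two conditions, and their difference.
#'
#' @param x a fitted `"readout"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.readout <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$signal
  graphics::matplot(s$time, cbind(s$cond_mean_match, s$cond_mean_nonmatch),
                    type = "l", lty = 1, col = c("firebrick", "navy"),
                    xlab = "time (ms)", ylab = "population signal",
                    main = sprintf("session '%s' (%s)", x$session_id,
                                   x$epoch), ...)
  graphics::legend("topleft", legend = c("match", "non-match"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n")
  graphics::plot(s$time, s$difference, type = "l", col = "magenta3",
                 xlab = "time (ms)", ylab = "match - non-match")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
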