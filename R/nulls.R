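new_null_ensemble <- function(samples, mode, seed, axis = NULL) {
  structure(list(samples = samples, mode = mode, nperm = nrow(samples),
                 seed = seed, axis = axis),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble [%s]: %d replicates x %d points (seed %s)\n",
              x$mode, x$nperm, ncol(x$samples), format(x$seed)))
  invisible(x)
}

# Permute `labels` until the subsets indexed by each element of `required`
# contain both classes (guards degenerate permutations on tiny data).
permute_labels_valid <- function(labels, required, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    p <- sample(labels)
    ok <- all(vapply(required,
                     function(ix) all(c(-1L, 1L) %in% p[ix]), TRUE))
    if (ok) return(p)
  }
  stop("could not find a label permutation with both classes in all subsets")
}

#' Class-label permutation null for the signal difference
#'
#' The full-pipeline null: in each replicate the match/non-match labels are
#' randomly permuted across all trials (the same permutation in the
#' training and the validation step), decoding weights are re-learned on
#' the permuted training labels, the validation signals are reconstructed
#' and condition-averaged with the permuted validation labels, and the
#' per-bin difference statistic is recorded. The ensemble is the
#' distribution of `match - non-match` differences expected when the
#' labels carry no information.
#'
#' @param x a [spike_train_set()].
#' @param split one element of [monte_carlo_splits()] (`train`/`valid`).
#' @param C SVM regularization used for every replicate.
#' @param kernel an [exp_kernel()].
#' @param window counting window for [spike_counts_zscored()] (default full).
#' @param nperm number of replicates (default 1000).
#' @param seed RNG seed; the ensemble is reproducible from it.
#' @param zscore_scope `"train"` (default) estimates z-scoring statistics on
#'   the training trials only; `"all"` uses every trial.
#' @return A `"null_ensemble"` with `nperm` x `K` samples,
#'   `mode = "label_perm"`.
#' @export
label_permutation_null <- function(x, split, C, kernel = exp_kernel(),
                                   window = NULL, nperm = 1000, seed = 1,
                                   zscore_scope = c("train", "all")) {
  stopifnot(inherits(x, "spike_train_set"), nperm >= 1)
  zscore_scope <- match.arg(zscore_scope)
  stats_trials <- if (zscore_scope == "train") split$train else NULL
  cm <- spike_counts_zscored(x, window, stats_trials = stats_trials)
  R <- convolved_spikes(x, kernel, trials = split$valid)
  xtr <- t(cm$zscores[, split$train, drop = FALSE])
  samples <- with_seed(seed, {
    t(vapply(seq_len(nperm), function(r) {
      p <- permute_labels_valid(x$labels, list(split$train, split$valid))
      m <- fit_linear_svm(xtr, p[split$train], C)
      nrm <- sqrt(sum(m$w^2))
      wn <- if (nrm > 0) m$w / nrm else m$w
      sig <- contract_weights(R, wn)
      center_and_average(sig, p[split$valid])$difference
    }, numeric(x$n_bins)))
  })
  new_null_ensemble(samples, "label_perm", seed, axis = time_axis(x))
}

#' Perturb a decoding weight vector
#'
#' Removes one source of information from the weights while keeping the
#' others intact:
#' * `"random"` - i.i.d. uniform draws over `[min(w), max(w)]` (removes all
#'   weight information, keeps the range);
#' * `"random_sign"` - keeps each weight's modulus, draws its sign at
#'   random;
#' * `"random_modulus"` - keeps each weight's sign, draws its modulus as
#'   the absolute value of a uniform draw over the weight range;
#' * `"binary"` - deterministic: every positive weight becomes `+a` and
#'   every negative weight `-a`, with `a = mean(|w|)`, preserving only the
#'   sign pattern at a common magnitude.
#'
#' @param weights a `"weight_vector"` or numeric vector.
#' @param mode perturbation mode (see above).
#' @param seed optional seed for the random modes.
#' @return A `"weight_vector"` with `method = "perturbed:<mode>"` and zero
#'   offset.
#' @export
perturb_weights <- function(weights,
                            mode = c("random", "random_sign",
                                     "random_modulus", "binary"),
                            seed = NULL) {
  mode <- match.arg(mode)
  w <- as_weights(weights)
  N <- length(w)
  draw <- function() {
    out <- switch(mode,
      random = stats::runif(N, min(w), max(w)),
      random_sign = sign(stats::runif(N, -1, 1)) * abs(w),
      random_modulus = sign(w) * abs(stats::runif(N, min(w), max(w))),
      binary = sign(w) * mean(abs(w)))
    out
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  new_weight_vector(out, 0, method = paste0("perturbed:", mode))
}

#' Permute spike timing within trials
#'
#' Randomly permutes, without repetition, the order of the time bins of a
#' spike train. The same bin permutation is applied to all neurons of a
#' trial, so per-neuron spike counts and zero-lag spike coincidences are
#' preserved while all temporal structure is destroyed; each trial gets an
#' independent permutation.
#'
#' @param x a neuron x bin matrix (single trial), a neuron x trial x bin
#'   array, or a [spike_train_set()].
#' @param seed optional RNG seed.
#' @return An object of the same type as `x` with time bins shuffled.
#' @export
permute_spike_timing <- function(x, seed = NULL) {
  doit <- function() {
    if (inherits(x, "spike_train_set")) {
      x$spikes <- permute_spike_timing(x$spikes)
      x
    } else if (is.matrix(x)) {
      x[, sample(ncol(x)), drop = FALSE]
    } else if (is.array(x) && length(dim(x)) == 3L) {
      for (j in seq_len(dim(x)[2L]))
        x[, j, ] <- x[, j, sample(dim(x)[3L]), drop = FALSE]
      x
    } else stop("`x` must be a matrix, 3-d array, or spike_train_set")
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

#' Per-bin significance of an observed series against a null ensemble
#'
#' Two-sided empirical p-values with add-one correction,
#' `p = (1 + #{|null| >= |obs|}) / (nperm + 1)`, per bin, flagged at
#' `alpha`; additionally reports the stricter "outside the null min/max"
#' criterion.
#'
#' @param observed numeric series (e.g. a signal difference per bin).
#' @param null a `"null_ensemble"` whose columns align with `observed`.
#' @param alpha significance level (default 0.05).
#' @return Object of class `"significance_mask"`: `p` (per-bin p-values,
#'   never below `1/(nperm+1)`), `flag` (`p <= alpha`), `outside` (beyond
#'   the null extremes), `alpha`, `nperm`.
#' @export
significance_mask <- function(observed, null, alpha = 0.05) {
  stopifnot(inherits(null, "null_ensemble"))
  S <- null$samples
  if (ncol(S) != length(observed)) stop("observed/null length mismatch")
  nperm <- nrow(S)
  exceed <- colSums(abs(S) >= rep(abs(observed), each = nperm))
  p <- (1 + exceed) / (nperm + 1)
  outside <- observed > apply(S, 2L, max) | observed < apply(S, 2L, min)
  structure(list(p = p, flag = p <= alpha, outside = outside,
                 alpha = alpha, nperm = nperm),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "Significance mask: %d/%d bins flagged at alpha = %g (nperm = %d)\n",
    sum(x$flag), length(x$flag), x$alpha, x$nperm))
  invisible(x)
}

#' Two-sample t-test on time-averaged per-trial signals
#'
#' Convenience parametric statistic: averages each trial's centered
#' population signal over time (optionally over a sub-window) and runs a
#' Welch two-sample t-test between the match and non-match trials. This is
#' an interpretation-level summary; the permutation machinery
#' ([label_permutation_null()] + [significance_mask()]) is the package's
#' primary inference path.
#'
#' @param signal a `"population_signal"`.
#' @param window optional half-open time window (in the signal's time
#'   units) over which to average; default the full window.
#' @return The [stats::t.test()] result.
#' @export
signal_ttest <- function(signal, window = NULL) {
  stopifnot(inherits(signal, "population_signal"))
  keep <- if (is.null(window)) rep(TRUE, length(signal$time))
          else signal$time >= window[1] & signal$time < window[2]
  avg <- rowMeans(signal$centered[, keep, drop = FALSE])
  stats::t.test(avg[signal$labels == 1L], avg[signal$labels == -1L])
}

#' Weight-perturbation null for the signal difference
#'
#' Distribution of the per-bin difference statistic when the decoding
#' weights are perturbed with [perturb_weights()] in each replicate while
#' spikes and labels stay intact. Quantifies how much of the
#' discrimination is carried by the perturbed-away component of the
#' weights.
#'
#' @param x a [spike_train_set()].
#' @param weights the learned (unperturbed) weights.
#' @param mode perturbation mode, see [perturb_weights()]; `"binary"` is
#'   deterministic, so its ensemble has identical rows.
#' @param trials validation trial indices (default all).
#' @param labels labels for those trials.
#' @param kernel an [exp_kernel()].
#' @param nperm replicates.
#' @param seed RNG seed.
#' @return A `"null_ensemble"` with `mode = "random_weights"`,
#'   `"random_sign"`, `"random_modulus"` or `"binary"`.
#' @export
weight_perturbation_null <- function(x, weights,
                                     mode = c("random", "random_sign",
                                              "random_modulus", "binary"),
                                     trials = NULL, labels = NULL,
                                     kernel = exp_kernel(), nperm = 1000,
                                     seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "spike_train_set"))
  if (is.null(trials)) trials <- seq_len(x$n_trials)
  if (is.null(labels)) labels <- x$labels[trials]
  R <- convolved_spikes(x, kernel, trials = trials)
  samples <- with_seed(seed, {
    t(vapply(seq_len(nperm), function(r) {
      wp <- perturb_weights(weights, mode)
      center_and_average(contract_weights(R, wp), labels)$difference
    }, numeric(x$n_bins)))
  })
  mode_tag <- if (mode == "random") "random_weights" else mode
  new_null_ensemble(samples, mode_tag, seed, axis = time_axis(x))
}

#' Spike-timing permutation null for the signal difference
#'
#' Distribution of the per-bin difference statistic when the order of time
#' bins is randomly permuted within each trial (shared across neurons)
#' before reconstruction, with the true weights and labels retained.
#' Destroys spike timing while preserving counts.
#'
#' @inheritParams weight_perturbation_null
#' @return A `"null_ensemble"` with `mode = "time_perm"`.
#' @export
timing_permutation_null <- function(x, weights, trials = NULL, labels = NULL,
                                    kernel = exp_kernel(), nperm = 1000,
                                    seed = 1) {
  stopifnot(inherits(x, "spike_train_set"))
  if (is.null(trials)) trials <- seq_len(x$n_trials)
  if (is.null(labels)) labels <- x$labels[trials]
  w <- as_weights(weights)
  spk <- x$spikes[, trials, , drop = FALSE]
  # project first: permuting bins commutes with the neuron sum
  Y <- matrix(matrix(w, 1L, dim(spk)[1L]) %*% matrix(spk, dim(spk)[1L]),
              length(trials), x$n_bins)
  samples <- with_seed(seed, {
    t(vapply(seq_len(nperm), function(r) {
      Yp <- t(apply(Y, 1L, function(row) row[sample(length(row))]))
      per_trial <- causal_filter_rows(Yp, kernel$values)
      center_and_average(per_trial, labels)$difference
    }, numeric(x$n_bins)))
  })
  new_null_ensemble(samples, "time_perm", seed, axis = time_axis(x))
}
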