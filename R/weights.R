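#' Default regularization grid for the linear SVM
#'
#' @return The numeric grid of soft-margin cost values searched by
#'   [select_regularization()].
#' @export
default_C_grid <- function() c(0.0012, 0.0015, 0.002, 0.005, 0.01, 0.05, 0.1, 0.5)

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

new_weight_vector <- function(weights, offset, method, regularization = NA_real_,
                              norm_applied = FALSE, extra = list()) {
  structure(c(list(weights = as.numeric(weights), offset = as.numeric(offset),
                   method = method, regularization = regularization,
                   norm_applied = norm_applied), extra),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Decoding weights (%s): %d neurons, %d positive / %d negative%s\n",
              x$method, length(x$weights), sum(x$weights > 0),
              sum(x$weights < 0),
              if (isTRUE(x$norm_applied)) ", L2-normalized" else ""))
  invisible(x)
}

#' Monte-Carlo cross-validation splits
#'
#' Generates repeated random half/half splits of trials into a training set
#' (weight learning) and a validation set (signal reconstruction),
#' stratified by class so both conditions appear on both sides. The
#' training set gets `floor(J/2)` trials; with odd trial counts the extra
#' trial goes to validation.
#'
#' @param labels class vector in `{-1, +1}`, one per trial.
#' @param n_runs number of independent splits (default 100).
#' @param seed integer seed; the same seed reproduces the same splits.
#' @return List of length `n_runs`; each element has `train`, `valid`
#'   (disjoint trial index vectors), `run_id` and `seed`.
#' @export
monte_carlo_splits <- function(labels, n_runs = 100, seed = 1) {
  labels <- as.integer(labels)
  J <- length(labels)
  idx_by_class <- split(seq_len(J), labels)
  if (length(idx_by_class) != 2L || any(lengths(idx_by_class) < 4L))
    stop("each class needs at least 4 trials for half/half splitting")
  n_c <- lengths(idx_by_class)
  n_train_c <- floor(n_c / 2)
  deficit <- floor(J / 2) - sum(n_train_c)
  if (deficit > 0) {  # odd class sizes: top up classes in order
    odd <- which(n_c %% 2 == 1L)
    n_train_c[odd[seq_len(deficit)]] <- n_train_c[odd[seq_len(deficit)]] + 1L
  }
  with_seed(seed, lapply(seq_len(n_runs), function(r) {
    train <- unlist(mapply(function(ix, k) sample(ix, k),
                           idx_by_class, n_train_c, SIMPLIFY = FALSE),
                    use.names = FALSE)
    train <- sort(train)
    list(train = train, valid = setdiff(seq_len(J), train),
         run_id = r, seed = seed)
  }))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity,
#' `BAC = TP/(2(TP+FN)) + TN/(2(TN+FP))`, which is robust to class
#' imbalance: chance level is 0.5 regardless of class proportions.
#'
#' @param predictions predicted classes in `{-1, +1}`.
#' @param labels true classes in `{-1, +1}`; both classes must occur.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, labels) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (length(predictions) != length(labels)) stop("length mismatch")
  if (!all(c(-1L, 1L) %in% labels)) stop("labels must contain both classes")
  tp <- sum(predictions == 1L & labels == 1L)
  fn <- sum(predictions != 1L & labels == 1L)
  tn <- sum(predictions == -1L & labels == -1L)
  fp <- sum(predictions != -1L & labels == -1L)
  0.5 * tp / (tp + fn) + 0.5 * tn / (tn + fp)
}

# Stratified k-fold assignment: per class, shuffled indices are dealt into
# folds of size n_c %/% k, remainders going to the first folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (ix in split(seq_along(labels), labels)) {
    n <- length(ix)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold[sample(ix)] <- rep(seq_len(k), times = sizes)
  }
  fold
}

# Fit libsvm and return the primal weight vector oriented so that
# sign(w.s + b) = +1 predicts class +1.
fit_linear_svm <- function(xmat, labels, C, tolerance = 1e-6) {
  y <- factor(labels, levels = c(-1, 1))
  fit <- e1071::svm(x = xmat, y = y, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the first class seen in the data
  if (fit$levels[fit$labels[1]] == "-1") { w <- -w; b <- -b }
  list(w = w, b = b, fit = fit)
}

#' Select the SVM regularization parameter by 5-fold cross-validation
#'
#' Evaluates each candidate soft-margin cost `C` with stratified k-fold
#' cross-validation on the supplied (training) trials, scoring folds by
#' balanced accuracy, and returns the candidate with the highest mean
#' fold score. Ties are broken toward the smallest `C` (strongest
#' regularization).
#'
#' @param zscores a [spike_counts_zscored()] result or a neuron x trial
#'   matrix of z-scored counts.
#' @param labels class vector in `{-1, +1}`.
#' @param grid candidate values, default [default_C_grid()].
#' @param n_folds number of folds (default 5).
#' @param seed seed for the fold shuffling.
#' @return The selected `C`, with the per-candidate mean fold balanced
#'   accuracies attached as attribute `"scores"`.
#' @export
select_regularization <- function(zscores, labels, grid = default_C_grid(),
                                  n_folds = 5, seed = 1) {
  z <- as_count_matrix_input(zscores, "zscores")
  labels <- as.integer(labels)
  if (length(grid) == 0L) stop("`grid` must be non-empty")
  grid <- sort(grid)
  xmat <- t(z)
  fold <- with_seed(seed, stratified_folds(labels, n_folds))
  scores <- vapply(grid, function(C) {
    bac <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (length(unique(labels[!tr])) < 2L || length(unique(labels[tr])) < 2L)
        stop("a fold lost one of the classes; use more trials or fewer folds")
      m <- fit_linear_svm(xmat[tr, , drop = FALSE], labels[tr], C)
      pred <- ifelse(drop(xmat[!tr, , drop = FALSE] %*% m$w) + m$b > 0, 1L, -1L)
      balanced_accuracy(pred, labels[!tr])
    }, 0.0)
    mean(bac)
  }, 0.0)
  best <- grid[which.max(scores)]  # which.max takes the first (smallest C) tie
  attr(best, "scores") <- stats::setNames(scores, grid)
  best
}

#' Learn multivariate decoding weights with a linear SVM
#'
#' Fits a soft-margin linear support vector machine to z-scored spike
#' counts and returns the feature weights, L2-normalized so that weight
#' vectors are comparable across sessions and regularization strengths.
#' The separating hyperplane is `w.s + b = 0`; the normalized weights give
#' each neuron's direction and relative magnitude of contribution to the
#' match/non-match discrimination, and the unnormalized offset is retained
#' for prediction.
#'
#' @param zscores a [spike_counts_zscored()] result or neuron x trial
#'   matrix.
#' @param labels class vector in `{-1, +1}`, at least 2 trials per class.
#' @param C soft-margin cost (> 0), typically chosen by
#'   [select_regularization()].
#' @param tolerance solver termination tolerance.
#' @return A `"weight_vector"` with `weights` (normalized, `||w|| = 1`),
#'   `weights_raw`, `offset` (raw scale), `offset_norm` (offset divided by
#'   `||w_raw||`, for use with the normalized weights), `method = "svm"`
#'   and `regularization = C`.
#' @export
learn_weights <- function(zscores, labels, C, tolerance = 1e-6) {
  z <- as_count_matrix_input(zscores, "zscores")
  labels <- as.integer(labels)
  if (min(table(factor(labels, levels = c(-1, 1)))) < 2L)
    stop("need at least 2 trials per class")
  if (C <= 0) stop("`C` must be positive")
  m <- fit_linear_svm(t(z), labels, C, tolerance)
  nrm <- sqrt(sum(m$w^2))
  wn <- if (nrm > 0) m$w / nrm else m$w
  new_weight_vector(wn, m$b, method = "svm", regularization = C,
                    norm_applied = TRUE,
                    extra = list(weights_raw = m$w,
                                 offset_norm = if (nrm > 0) m$b / nrm else m$b,
                                 norm = nrm))
}

#' Univariate decoding weights from the area under the ROC curve
#'
#' Scores each neuron independently by the area under the ROC curve (AUC)
#' of its spike counts for discriminating "match" (+1) from "non-match"
#' (-1) trials, using the tie-aware pair-counting definition (ties count
#' 1/2). The chance level 1/2 is subtracted so uninformative neurons get
#' weight 0, and the centered vector is scaled to unit L2 norm so the
#' weights are comparable to the multivariate SVM weights.
#'
#' @param counts a [spike_counts_zscored()] result (its raw `counts` are
#'   used) or a neuron x trial count matrix.
#' @param labels class vector in `{-1, +1}`.
#' @return A `"weight_vector"` with `method = "auc"`, zero offset, and the
#'   raw per-neuron `auc` values attached.
#' @export
auc_weights <- function(counts, labels) {
  cts <- as_count_matrix_input(counts, "counts")
  labels <- as.integer(labels)
  pos <- labels == 1L
  if (!any(pos) || !all(c(-1L, 1L) %in% labels))
    stop("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- apply(cts, 1L, function(v) {
    r <- rank(v)  # midranks implement the ties-count-1/2 convention
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  centered <- auc - 0.5
  nrm <- sqrt(sum(centered^2))
  w <- if (nrm > 0) centered / nrm else centered
  new_weight_vector(w, 0, method = "auc", norm_applied = nrm > 0,
                    extra = list(auc = auc, norm = nrm))
}

#' Write decoding weights as delimited text
#'
#' One row per (cross-validation run, neuron), tab-separated, with columns
#' session_id, cv_run, neuron_id, weight, sign, method, C.
#'
#' @param weights a `"weight_vector"` or list of them (one per CV run).
#' @param path output file path.
#' @param session_id session identifier written into each row.
#' @param neuron_ids optional neuron identifiers.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, session_id = "session",
                          neuron_ids = NULL) {
  if (inherits(weights, "weight_vector")) weights <- list(weights)
  rows <- do.call(rbind, lapply(seq_along(weights), function(r) {
    w <- weights[[r]]
    n <- length(w$weights)
    ids <- if (is.null(neuron_ids)) paste0("n", seq_len(n)) else neuron_ids
    data.frame(session_id = session_id, cv_run = r, neuron_id = ids,
               weight = w$weights, sign = sign(w$weights), method = w$method,
               C = w$regularization)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
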