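#' Analysis configuration for the full pipeline
#'
#' Collects the tunable parameters of [run_full_analysis()]. Defaults are
#' the package's standard operating point: 20-ms read-out time constant,
#' 1000 permutation replicates, 100 cross-validation runs, alpha 0.05.
#'
#' @param kernel_rate exponential kernel decay rate per ms.
#' @param nperm permutation replicates for every null model.
#' @param n_cv Monte-Carlo cross-validation runs.
#' @param C fixed SVM regularization, or `NULL` to select from `C_grid`.
#' @param C_grid regularization grid.
#' @param alpha significance level for the per-bin masks.
#' @param window spike-counting window (default full window).
#' @param zscore_scope `"train"` or `"all"`.
#' @param analyses which blocks to run; any subset of
#'   `"signs"`, `"perturbations"`, `"univariate"`, `"ccf"`, `"layers"`
#'   (the main signal + label-permutation null always runs).
#' @param seed master seed; all block seeds derive from it.
#' @return Object of class `"analysis_config"`.
#' @export
analysis_config <- function(kernel_rate = 1 / 20, nperm = 1000, n_cv = 100,
                            C = NULL, C_grid = default_C_grid(),
                            alpha = 0.05, window = NULL,
                            zscore_scope = "train",
                            analyses = c("signs", "perturbations",
                                         "univariate", "ccf", "layers"),
                            seed = 1) {
  structure(list(kernel_rate = kernel_rate, nperm = nperm, n_cv = n_cv,
                 C = C, C_grid = C_grid, alpha = alpha, window = window,
                 zscore_scope = zscore_scope, analyses = analyses,
                 seed = seed),
            class = "analysis_config")
}

summarize_mask <- function(mask) {
  list(n_flagged = sum(mask$flag), n_bins = length(mask$flag),
       flag_rate = mean(mask$flag), min_p = min(mask$p),
       n_outside = sum(mask$outside))
}

analyze_epoch <- function(x, cfg, lfp = NULL, lfp_spacing = NULL) {
  kernel <- exp_kernel(cfg$kernel_rate)
  fit <- readout(x, n_cv = cfg$n_cv, C = cfg$C, C_grid = cfg$C_grid,
                 kernel = kernel, window = cfg$window,
                 zscore_scope = cfg$zscore_scope, seed = cfg$seed)
  sp <- fit$splits[[1]]
  valid <- sp$valid; vlab <- x$labels[valid]
  # representative single-run weights for the subpopulation analyses
  w1 <- fit$weights_runs[1, ]
  null <- label_permutation_null(x, sp, C = fit$C, kernel = kernel,
                                 window = cfg$window, nperm = cfg$nperm,
                                 seed = cfg$seed + 1,
                                 zscore_scope = cfg$zscore_scope)
  mask <- significance_mask(fit$signal$difference, null, cfg$alpha)
  report <- list(
    session_id = x$session_id, epoch = x$epoch,
    n_neurons = x$n_neurons, n_trials = x$n_trials,
    C = fit$C, mean_bac = mean(fit$bac), sd_bac = stats::sd(fit$bac),
    weights = fit$weights,
    n_plus = sum(fit$weights > 0), n_minus = sum(fit$weights < 0),
    signal = fit$signal,
    null = list(mode = null$mode, nperm = null$nperm, seed = null$seed),
    significance = summarize_mask(mask))
  out <- list(fit = fit, null = null, mask = mask, report = report)

  if ("signs" %in% cfg$analyses) {
    ss <- sign_split(w1)
    sig_p <- subpop_signal(x, w1, ss$plus, kernel, trials = valid)
    sig_m <- subpop_signal(x, w1, ss$minus, kernel, trials = valid)
    out$signs <- list(split = ss, plus = sig_p, minus = sig_m)
    out$report$signs <- list(
      n_plus = ss$plus$n_sub, n_minus = ss$minus$n_sub,
      f_plus = ss$plus$correction, f_minus = ss$minus$correction,
      mean_abs_diff_plus = mean(abs(sig_p$difference)),
      mean_abs_diff_minus = mean(abs(sig_m$difference)))
  }

  if ("perturbations" %in% cfg$analyses) {
    modes <- c("random", "random_sign", "random_modulus")
    perts <- lapply(seq_along(modes), function(i)
      weight_perturbation_null(x, w1, modes[i], trials = valid,
                               kernel = kernel, nperm = cfg$nperm,
                               seed = cfg$seed + 10 + i))
    names(perts) <- modes
    timing <- timing_permutation_null(x, w1, trials = valid,
                                      kernel = kernel, nperm = cfg$nperm,
                                      seed = cfg$seed + 20)
    wb <- perturb_weights(w1, "binary")
    sig1 <- center_and_average(
      reconstruct_trials(x, w1, kernel, valid), vlab)
    sigb <- center_and_average(
      reconstruct_trials(x, wb, kernel, valid), vlab)
    out$perturbations <- list(ensembles = perts, timing = timing,
                              binary = sigb, regular = sig1)
    out$report$perturbations <- c(
      lapply(perts, function(e)
        list(mode = e$mode, nperm = e$nperm,
             mean_abs_timeavg = mean(abs(rowMeans(e$samples))))),
      list(time_perm = list(mode = timing$mode, nperm = timing$nperm,
                            mean_abs_timeavg =
                              mean(abs(rowMeans(timing$samples)))),
           binary_cor = stats::cor(sigb$difference, sig1$difference)))
  }

  if ("univariate" %in% cfg$analyses) {
    cm_tr <- spike_counts_zscored(x, cfg$window, stats_trials = sp$train)
    aucw <- auc_weights(cm_tr$counts[, sp$train, drop = FALSE],
                        x$labels[sp$train])
    uni <- univariate_signals(x, aucw, kernel, trials = valid)
    out$univariate <- list(weights = aucw, signals = uni)
    out$report$univariate <- list(
      auc = aucw$auc,
      timeavg_abs_diff = vapply(uni, function(s)
        mean(abs(s$difference)), 0.0))
  }

  if ("ccf" %in% cfg$analyses) {
    ss <- sign_split(w1)
    if (ss$plus$valid && ss$minus$valid) {
      wp <- ifelse(ss$plus$mask, w1, 0) * ss$plus$correction
      wm <- ifelse(ss$minus$mask, w1, 0) * ss$minus$correction
      A <- reconstruct_trials(x, wp, kernel, valid)
      B <- reconstruct_trials(x, wm, kernel, valid)
      ccf <- ccf_trial_averaged(A, B, vlab, "both", pair = "plus:minus")
      ccf_null <- assignment_ccf_null(x, w1, "pool", trials = valid,
                                      kernel = kernel, nperm = cfg$nperm,
                                      seed = cfg$seed + 30)
      lag0 <- which(ccf$lags == 0)
      nv <- ccf_null$samples[, lag0]
      out$ccf <- list(observed = ccf, null = ccf_null)
      out$report$ccf <- list(
        pair = "plus:minus", lag0 = ccf$values[lag0],
        null_mode = ccf_null$mode, nperm = ccf_null$nperm,
        lag0_null_lo = min(nv, na.rm = TRUE),
        lag0_null_hi = max(nv, na.rm = TRUE),
        outside_null = ccf$values[lag0] < min(nv, na.rm = TRUE) |
          ccf$values[lag0] > max(nv, na.rm = TRUE))
    } else {
      out$report$ccf <- list(skipped = "one sign pool is empty")
    }
  }

  if ("layers" %in% cfg$analyses) {
    if (is.null(lfp) || is.null(x$depths)) {
      warning("layer analysis requested but LFP or neuron depths missing; skipped")
      out$report$layers <- list(skipped = "no LFP or neuron depths")
    } else {
      csd <- compute_csd(lfp, lfp_spacing)
      la <- assign_neurons(x$depths, layer_borders(csd))
      ls <- layer_split(w1, la)
      layer_sigs <- lapply(ls, function(spec)
        suppressWarnings(subpop_signal(x, w1, spec, kernel,
                                       trials = valid)))
      out$layers <- list(csd = csd, assignment = la, signals = layer_sigs)
      out$report$layers <- list(
        borders = as.list(la$borders),
        n_per_layer = as.list(table(factor(la$neuron_layers,
                                           levels = c("SG", "G", "IG")))),
        timeavg_abs_diff = lapply(layer_sigs, function(s)
          if (isTRUE(s$valid)) mean(abs(s$difference)) else NA_real_))
    }
  }
  out
}

#' Run the full read-out analysis of a session
#'
#' Orchestrates, per epoch: the read-out fit across Monte-Carlo CV runs;
#' the class-label permutation null and per-bin significance mask of the
#' signal difference; sign-split (plus/minus) signals; the four
#' weight/timing perturbation analyses plus the binary-weight signal;
#' univariate AUC-based single-neuron signals; the plus x minus
#' cross-correlation with its random-assignment null; and, when a laminar
#' LFP and neuron depths are available, CSD-based layer assignment with
#' layer-specific signals. Every null block records its mode, `nperm` and
#' seed, and the whole run is reproducible from the configuration seed.
#'
#' @param session a `"synthetic_session"`, a named list of
#'   [spike_train_set()]s (epochs), or a single `spike_train_set`.
#' @param config an [analysis_config()].
#' @param lfp optional channels x time x trials LFP array (taken from the
#'   session if present).
#' @param lfp_spacing inter-channel spacing for the LFP.
#' @return Object of class `"readout_report"`: per-epoch full results
#'   (`$epochs`), a JSON-ready summary (`$summary`), and the
#'   configuration (`$config`).
#' @export
run_full_analysis <- function(session, config = analysis_config(),
                              lfp = NULL, lfp_spacing = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (inherits(session, "synthetic_session")) {
    if (is.null(lfp)) {
      lfp <- session$lfp
      lfp_spacing <- session$config$channel_spacing
    }
    epochs <- list(target = session$target, test = session$test)
  } else if (inherits(session, "spike_train_set")) {
    epochs <- stats::setNames(list(session), session$epoch)
  } else epochs <- session
  results <- lapply(epochs, analyze_epoch, cfg = config, lfp = lfp,
                    lfp_spacing = lfp_spacing)
  summary <- list(config = unclass(config),
                  epochs = lapply(results, `[[`, "report"))
  structure(list(epochs = results, summary = summary, config = config),
            class = "readout_report")
}

#' @export
print.readout_report <- function(x, ...) {
  cat("Read-out analysis report\n")
  for (nm in names(x$epochs)) {
    rp <- x$epochs[[nm]]$report
    cat(sprintf(
      " epoch %-7s BAC %.3f, %d/%d bins flagged (alpha %.2g, nperm %d)\n",
      nm, rp$mean_bac, rp$significance$n_flagged, rp$significance$n_bins,
      x$config$alpha, x$config$nperm))
  }
  invisible(x)
}

#' Write a report summary as JSON
#'
#' Serializes the JSON-ready `$summary` of a [run_full_analysis()] report.
#' The output is deterministic given the same session, configuration and
#' seed.
#'
#' @param report a `"readout_report"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report$summary, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
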