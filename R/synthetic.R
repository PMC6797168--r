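#' Configuration for a synthetic recording session
#'
#' Describes a session of simultaneously recorded neurons in a two-
#' condition (match / non-match) discrimination setting with planted,
#' recoverable structure. Defaults emulate a typical laminar-probe
#' session: a couple dozen units, on the order of a hundred trials per
#' condition, 400 ms analysis windows at 1-ms resolution, and a
#' condition-dependent rate modulation confined to the late part of the
#' test window, with neuron-specific sign (the plus/minus structure).
#'
#' @param n_neurons number of simultaneously recorded neurons.
#' @param n_trials_per_condition trials per condition (match and
#'   non-match).
#' @param K number of 1-ms bins per window.
#' @param baseline_rates per-neuron baseline firing rate in Hz (recycled).
#' @param modulation_depth condition effect in Hz added (plus neurons) or
#'   subtracted (minus neurons) in match trials inside `effect_window`.
#' @param effect_window half-open interval in ms where the effect acts.
#' @param plus_fraction fraction of neurons with positive planted sign.
#' @param shared_latent_sd SD in Hz of a trial-wise shared latent rate
#'   fluctuation (smoothed Gaussian process, 20-ms scale) loaded with
#'   opposite sign by the plus and minus pools (a differential common
#'   input); 0 disables it.
#' @param layer_sizes integer vector `(SG, G, IG)` summing to `n_neurons`.
#' @param n_channels laminar probe channels for the LFP.
#' @param channel_spacing inter-channel spacing (micrometres).
#' @param lfp_snr ratio of LFP signal amplitude to single-trial noise SD.
#' @param seed integer seed; the session is reproducible from it.
#' @return Object of class `"session_config"` (a validated list).
#' @export
session_config <- function(n_neurons = 20, n_trials_per_condition = 100,
                           K = 400, baseline_rates = 5,
                           modulation_depth = 10,
                           effect_window = c(200, 400),
                           plus_fraction = 0.55, shared_latent_sd = 0,
                           layer_sizes = NULL, n_channels = 16,
                           channel_spacing = 100, lfp_snr = 5, seed = 1) {
  baseline_rates <- rep_len(baseline_rates, n_neurons)
  if (any(baseline_rates < 0)) stop("rates must be non-negative")
  if (plus_fraction < 0 || plus_fraction > 1)
    stop("`plus_fraction` must be in [0, 1]")
  if (is.null(layer_sizes)) {
    base <- n_neurons %/% 3
    layer_sizes <- c(SG = base + (n_neurons %% 3 > 0),
                     G = base + (n_neurons %% 3 > 1), IG = base)
  }
  if (sum(layer_sizes) != n_neurons)
    stop("`layer_sizes` must sum to `n_neurons`")
  if (n_channels < 8) stop("need at least 8 laminar channels")
  structure(list(n_neurons = n_neurons,
                 n_trials_per_condition = n_trials_per_condition, K = K,
                 baseline_rates = baseline_rates,
                 modulation_depth = modulation_depth,
                 effect_window = effect_window,
                 plus_fraction = plus_fraction,
                 shared_latent_sd = shared_latent_sd,
                 layer_sizes = stats::setNames(layer_sizes,
                                               c("SG", "G", "IG")),
                 n_channels = n_channels,
                 channel_spacing = channel_spacing, lfp_snr = lfp_snr,
                 seed = seed),
            class = "session_config")
}

# Smoothed standard Gaussian process: white noise convolved with a
# Gaussian kernel (sd `scale` bins) and rescaled to unit marginal SD.
smoothed_latent <- function(K, scale = 20) {
  tau <- seq.int(-3 * scale, 3 * scale)
  w <- exp(-tau^2 / (2 * scale^2)); w <- w / sum(w)
  z <- stats::rnorm(K + length(tau) - 1)
  sm <- drop(stats::filter(z, w, sides = 2))
  sm <- sm[!is.na(sm)][seq_len(K)]
  sm / sqrt(sum(w^2))
}

bernoulli_epoch <- function(cfg, labels, signs, effect) {
  N <- cfg$n_neurons; J <- length(labels); K <- cfg$K
  eff_bins <- seq_len(K) - 1 >= cfg$effect_window[1] &
    seq_len(K) - 1 < cfg$effect_window[2]
  # per-neuron x bin rate, by condition
  base <- matrix(cfg$baseline_rates, N, K)
  rate_m <- base
  if (effect)
    rate_m[, eff_bins] <- rate_m[, eff_bins] + signs * cfg$modulation_depth
  check_p <- function(r) {
    p <- pmax(r, 0) / 1000  # 1-ms bins
    if (any(p > 1)) stop("per-bin spike probability exceeds 1")
    p
  }
  spk <- array(0L, dim = c(N, J, K))
  if (cfg$shared_latent_sd > 0) {
    # differential common input: the two pools load the latent with
    # opposite sign, decorrelating the temporal shapes of the weighted
    # pool signals
    loadings <- signs * cfg$shared_latent_sd
    for (j in seq_len(J)) {
      lat <- smoothed_latent(K)
      r <- (if (labels[j] == 1L) rate_m else base) +
        outer(loadings, lat)
      spk[, j, ] <- stats::rbinom(N * K, 1L, check_p(r))
    }
  } else {
    p_m <- check_p(rate_m); p_nm <- check_p(base)
    for (j in seq_len(J))
      spk[, j, ] <- stats::rbinom(N * K, 1L,
                                  if (labels[j] == 1L) p_m else p_nm)
  }
  spk
}

#' Generate a synthetic recording session
#'
#' Simulates parallel spike trains for two epochs with per-bin Bernoulli
#' spiking (discrete-time Poisson at 1-ms resolution): a *target* epoch
#' with no condition effect, and a *test* epoch where, inside the effect
#' window, match trials shift each modulated neuron's rate by the planted
#' modulation depth with a neuron-specific sign (plus neurons up, minus
#' neurons down). An optional shared latent adds trial-wise differential
#' rate fluctuations (opposite loadings in the two pools), displacing the
#' pools' cross-correlation away from its random-assignment null. Neurons are placed at probe depths
#' consistent with the planted layer sizes, and a laminar LFP with the
#' matching sink/source pattern is generated via
#' [generate_laminar_lfp()].
#'
#' @param config a [session_config()].
#' @return Object of class `"synthetic_session"`: `target` and `test`
#'   ([spike_train_set()]s, labels `-1` non-match then `+1` match), `lfp`
#'   (channels x time x trials array), and `truth` (planted `signs`,
#'   `modulation_depth`, `layers`, `depths`, `borders`, `sink_depth`,
#'   `latent_loadings`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  cfg <- config
  with_seed(cfg$seed, {
    J <- 2L * cfg$n_trials_per_condition
    labels <- rep(c(-1L, 1L), each = cfg$n_trials_per_condition)
    n_plus <- round(cfg$plus_fraction * cfg$n_neurons)
    signs <- sample(c(rep(1, n_plus), rep(-1, cfg$n_neurons - n_plus)))
    layers <- sample(rep(c("SG", "G", "IG"), times = cfg$layer_sizes))
    geom <- lfp_geometry(cfg)
    depths <- vapply(layers, function(l) switch(l,
      SG = stats::runif(1, 0, geom$upper),
      G = stats::runif(1, geom$upper, geom$lower),
      IG = stats::runif(1, geom$lower, geom$span)), 0.0)
    target <- bernoulli_epoch(cfg, labels, signs, effect = FALSE)
    test <- bernoulli_epoch(cfg, labels, signs, effect = TRUE)
    lfp <- laminar_lfp_array(cfg, geom, n_trials = J)
    structure(list(
      target = spike_train_set(target, labels, epoch = "target",
                               session_id = sprintf("synth%d", cfg$seed),
                               depths = depths),
      test = spike_train_set(test, labels, epoch = "test",
                             session_id = sprintf("synth%d", cfg$seed),
                             depths = depths),
      lfp = lfp,
      config = cfg,
      truth = list(signs = signs,
                   modulation_depth = cfg$modulation_depth,
                   layers = layers, depths = depths,
                   borders = c(upper = geom$upper, lower = geom$lower),
                   sink_depth = geom$sink_depth,
                   latent_loadings = signs * cfg$shared_latent_sd)),
      class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic session (seed %d): %d neurons, %d trials/condition, %d bins\n",
    cfg$seed, cfg$n_neurons, cfg$n_trials_per_condition, cfg$K))
  cat(sprintf("  planted: %d plus / %d minus, %g Hz modulation in [%g, %g) ms\n",
              sum(x$truth$signs > 0), sum(x$truth$signs < 0),
              cfg$modulation_depth, cfg$effect_window[1],
              cfg$effect_window[2]))
  invisible(x)
}

# Probe geometry: the planted G layer is centred mid-probe; its borders
# sit one depth-sigma either side of the sink (where the second spatial
# derivative of a Gaussian LFP profile changes sign).
lfp_geometry <- function(cfg) {
  span <- cfg$channel_spacing * (cfg$n_channels - 1)
  sink_depth <- span / 2
  sigma_z <- 1.5 * cfg$channel_spacing
  list(span = span, sink_depth = sink_depth, sigma_z = sigma_z,
       upper = sink_depth - sigma_z, lower = sink_depth + sigma_z)
}

laminar_lfp_array <- function(cfg, geom, n_trials) {
  depths <- cfg$channel_spacing * (seq_len(cfg$n_channels) - 1)
  profile <- -exp(-(depths - geom$sink_depth)^2 / (2 * geom$sigma_z^2))
  tt <- seq_len(cfg$K) - 1
  temporal <- exp(-(tt - 60)^2 / (2 * 15^2))  # evoked transient at 60 ms
  signal <- outer(profile, temporal)
  noise_sd <- 1 / cfg$lfp_snr
  lfp <- array(stats::rnorm(cfg$n_channels * cfg$K * n_trials,
                            sd = noise_sd),
               dim = c(cfg$n_channels, cfg$K, n_trials))
  lfp + as.vector(signal)
}

#' Generate a laminar LFP with a planted sink/source pattern
#'
#' Builds trial-wise local field potentials whose trial-averaged CSD shows
#' a focal sink (a negative Gaussian-in-depth potential deflection)
#' centred on the planted granular layer, peaking 60 ms after onset,
#' flanked by sources, plus white noise at the configured SNR. The true
#' granular borders sit one depth-sigma either side of the sink, where the
#' second spatial derivative of the Gaussian profile changes sign.
#'
#' @param config a [session_config()].
#' @param n_trials number of LFP trials (default twice
#'   `n_trials_per_condition`).
#' @return List with `lfp` (channels x time x trials),
#'   `spacing`, and `truth` (`sink_depth`, `borders`).
#' @export
generate_laminar_lfp <- function(config,
                                 n_trials = 2L *
                                   config$n_trials_per_condition) {
  stopifnot(inherits(config, "session_config"))
  geom <- lfp_geometry(config)
  lfp <- with_seed(config$seed,
                   laminar_lfp_array(config, geom, n_trials))
  list(lfp = lfp, spacing = config$channel_spacing,
       truth = list(sink_depth = geom$sink_depth,
                    borders = c(upper = geom$upper, lower = geom$lower)))
}
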