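# Naive reference implementations used as independent oracles. These are
# deliberately written as plain double/triple loops over the defining sums,
# sharing no code with the package internals.

# Population signal of one trial: double sum over kernel lags of the
# weighted spike vector.
oracle_reconstruct <- function(spikes_trial, w, u) {
  K <- ncol(spikes_trial)
  L <- length(u)
  x <- numeric(K)
  for (k in seq_len(K)) {
    acc <- 0
    for (tau in 0:(L - 1)) {
      if (k - tau >= 1) acc <- acc + sum(w * spikes_trial[, k - tau]) * u[tau + 1]
    }
    x[k] <- acc
  }
  x
}

# Smoothed population PSTH by direct summation.
oracle_psth <- function(spikes, sigma_sq, halfwidth) {
  d <- dim(spikes)
  raw <- numeric(d[3])
  for (k in seq_len(d[3])) raw[k] <- sum(spikes[, , k]) / (d[1] * d[2])
  tau <- -halfwidth:halfwidth
  w <- exp(-tau^2 / (2 * sigma_sq)); w <- w / sum(w)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    acc <- 0
    for (i in seq_along(tau)) {
      src <- k - tau[i]
      if (src >= 1 && src <= d[3]) acc <- acc + raw[src] * w[i]
    }
    out[k] <- acc
  }
  out
}

# Per-neuron z-scores by looping over neurons (sample variance, ddof 1).
oracle_zscores <- function(counts, stats_trials) {
  z <- counts * NA_real_
  for (n in seq_len(nrow(counts))) {
    v <- counts[n, stats_trials]
    mu <- mean(v)
    s2 <- sum((v - mu)^2) / (length(v) - 1)
    z[n, ] <- (counts[n, ] - mu) / sqrt(s2)
  }
  z
}

# AUC by O(J^2) pair counting, ties counted 1/2.
oracle_auc <- function(v, labels) {
  pos <- v[labels == 1]
  neg <- v[labels == -1]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Raw lagged-product cross-correlation by an O(K^2) loop, with the
# negative-lag symmetry rule.
oracle_ccf <- function(x, y) {
  K <- length(x)
  pos <- function(a, b, tau) {
    acc <- 0
    for (k in 0:(K - tau - 1)) acc <- acc + a[k + 1] * b[k + tau + 1]
    acc
  }
  lags <- -(K - 1):(K - 1)
  vals <- numeric(length(lags))
  for (i in seq_along(lags)) {
    tau <- lags[i]
    vals[i] <- if (tau >= 0) pos(x, y, tau) else pos(y, x, -tau)
  }
  vals / sqrt(pos(x, x, 0) * pos(y, y, 0))
}

# Small random spike tensor with both labels present.
random_sts <- function(N = 3, J = 10, K = 60, p = 0.08, seed = 1,
                       epoch = "test") {
  set.seed(seed)
  spk <- array(rbinom(N * J * K, 1, p), dim = c(N, J, K))
  labels <- c(-1, 1, sample(c(-1, 1), J - 2, replace = TRUE))
  spike_train_set(spk, labels, epoch = epoch)
}

# Separable toy session: neurons fire more (or less, by sign) in match
# trials over the whole window; counts-level effect, no temporal structure.
separable_sts <- function(N = 6, J_per = 30, K = 100, base = 0.05,
                          delta = 0.04, signs = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(signs)) signs <- rep(c(1, -1), length.out = N)
  labels <- rep(c(-1, 1), each = J_per)
  spk <- array(0L, dim = c(N, 2 * J_per, K))
  for (j in seq_len(2 * J_per)) {
    p <- base + (labels[j] == 1) * signs * delta
    for (n in seq_len(N)) spk[n, j, ] <- rbinom(K, 1, max(min(p[n], 1), 0))
  }
  spike_train_set(spk, labels)
}
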