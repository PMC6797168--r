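test_that("weight perturbations preserve exactly the stated structure", {
  w <- c(0.6, -0.8, 0.1, -0.2, 0.05)
  ps <- perturb_weights(w, "random_sign", seed = 3)
  expect_equal(abs(ps$weights), abs(w))
  pm <- perturb_weights(w, "random_modulus", seed = 3)
  expect_equal(sign(pm$weights), sign(w))
  pr <- perturb_weights(w, "random", seed = 3)
  expect_true(all(pr$weights >= min(w) & pr$weights <= max(w)))
  # binary: +/- a with a = mean(|w|)
  pb <- perturb_weights(c(0.6, -0.8), "binary")
  expect_equal(pb$weights, c(0.7, -0.7))
  expect_error(perturb_weights(w, "bogus"))
  # seeded modes reproduce
  expect_equal(perturb_weights(w, "random", seed = 5)$weights,
               perturb_weights(w, "random", seed = 5)$weights)
})

test_that("spike-timing permutation preserves counts and coincidences", {
  x <- random_sts(N = 4, J = 6, K = 50, p = 0.15, seed = 19)
  y <- permute_spike_timing(x, seed = 7)
  expect_equal(rowSums(y$spikes, dims = 2), rowSums(x$spikes, dims = 2))
  # zero-lag pairwise coincidences unchanged (shared permutation)
  co <- function(s) vapply(seq_len(6), function(j)
    sum(s[1, j, ] * s[2, j, ]), 0.0)
  expect_equal(co(y$spikes), co(x$spikes))
  # single-trial matrix form permutes columns
  m <- x$spikes[, 1, ]
  pm <- permute_spike_timing(m, seed = 1)
  expect_equal(rowSums(pm), rowSums(m))
  # time-averaged reconstructed signal moves only by a kernel-edge amount
  w <- c(0.4, -0.2, 0.3, 0.1)
  k <- exp_kernel(1 / 20)
  s_before <- sum(reconstruct_trial(m, w, k))
  s_after <- sum(reconstruct_trial(pm, w, k))
  bound <- sum(abs(w)) * max(rowSums(m)) * k$area  # loose kernel-mass bound
  expect_lt(abs(s_after - s_before), bound)
})

test_that("significance mask computes add-one empirical p-values", {
  samples <- matrix(rnorm(200 * 10), 200, 10)
  null <- popsignal:::new_null_ensemble(samples, "label_perm", 1)
  # observed equal to a null sample: not outside the distribution
  obs <- samples[5, ]
  m <- significance_mask(obs, null)
  expect_true(all(!m$outside))
  expect_true(all(m$p >= 1 / 201))
  # observed beyond every null value: minimal p, flagged
  m2 <- significance_mask(rep(100, 10), null)
  expect_equal(m2$p, rep(1 / 201, 10))
  expect_true(all(m2$flag))
  expect_true(all(m2$outside))
})

test_that("label-permutation null is centered and reproducible", {
  x <- separable_sts(N = 5, J_per = 20, K = 80, delta = 0.05, seed = 23)
  sp <- monte_carlo_splits(x$labels, 1, seed = 3)[[1]]
  n1 <- label_permutation_null(x, sp, C = 0.1, nperm = 60, seed = 11)
  expect_equal(dim(n1$samples), c(60, 80))
  # mean statistic ~ 0 bin-wise: |mean| below 3 SE for nearly all bins
  se <- apply(n1$samples, 2, sd) / sqrt(60)
  expect_gt(mean(abs(colMeans(n1$samples)) < 3 * se), 0.95)
  # same seed, identical ensemble; nperm = 1 gives a single row
  n2 <- label_permutation_null(x, sp, C = 0.1, nperm = 60, seed = 11)
  expect_identical(n1$samples, n2$samples)
  n3 <- label_permutation_null(x, sp, C = 0.1, nperm = 1, seed = 2)
  expect_equal(nrow(n3$samples), 1)
})

test_that("flag rate under a true null is close to alpha", {
  # no-effect sessions: per-bin flags at alpha = 0.05 appear at ~ chance
  rates <- vapply(1:8, function(s) {
    x <- separable_sts(N = 4, J_per = 15, K = 60, delta = 0, seed = 100 + s)
    sp <- monte_carlo_splits(x$labels, 1, seed = s)[[1]]
    cm <- spike_counts_zscored(x, stats_trials = sp$train)
    wv <- learn_weights(cm$zscores[, sp$train], x$labels[sp$train], C = 0.1)
    sig <- center_and_average(
      reconstruct_trials(x, wv$weights, trials = sp$valid),
      x$labels[sp$valid])
    nul <- label_permutation_null(x, sp, C = 0.1, nperm = 100,
                                  seed = 200 + s)
    mean(significance_mask(sig$difference, nul, 0.05)$flag)
  }, 0.0)
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.12)
})

test_that("time-averaged t-test detects a planted effect and not noise", {
  x <- separable_sts(N = 5, J_per = 30, K = 100, delta = 0.05, seed = 71)
  w <- learn_weights(spike_counts_zscored(x), x$labels, C = 0.1)$weights
  sig <- center_and_average(reconstruct_trials(x, w), x$labels)
  tt <- signal_ttest(sig)
  expect_s3_class(tt, "htest")
  expect_lt(tt$p.value, 1e-4)
  x0 <- separable_sts(N = 5, J_per = 30, K = 100, delta = 0, seed = 72)
  sig0 <- center_and_average(reconstruct_trials(x0, w), x0$labels)
  expect_gt(signal_ttest(sig0)$p.value, 0.001)
})

test_that("perturbation ensembles have the right shape and determinism", {
  x <- separable_sts(N = 5, J_per = 15, K = 60, delta = 0.05, seed = 61)
  w <- learn_weights(spike_counts_zscored(x), x$labels, C = 0.1)$weights
  e1 <- weight_perturbation_null(x, w, "random_sign", nperm = 20, seed = 5)
  expect_equal(dim(e1$samples), c(20, 60))
  expect_equal(e1$mode, "random_sign")
  e2 <- weight_perturbation_null(x, w, "random_sign", nperm = 20, seed = 5)
  expect_identical(e1$samples, e2$samples)
  # binary mode is deterministic: all rows identical
  eb <- weight_perturbation_null(x, w, "binary", nperm = 5, seed = 1)
  expect_equal(eb$samples[1, ], eb$samples[5, ])
  et <- timing_permutation_null(x, w, nperm = 10, seed = 3)
  expect_equal(dim(et$samples), c(10, 60))
})
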