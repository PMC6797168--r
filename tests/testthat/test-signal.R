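test_that("exponential kernel has the stated closed form", {
  k <- exp_kernel(1 / 20)
  expect_equal(k$values[1], 1)
  expect_equal(k$values[21], exp(-1))
  expect_equal(k$support_length, 100)
  expect_true(all(diff(k$values) < 0))
  kn <- exp_kernel(1 / 20, normalized = TRUE)
  expect_equal(sum(kn$values), 1, tolerance = 1e-12)
  # delta-kernel limit: support 1 reduces to the raw weighted spike train
  x <- random_sts(N = 3, J = 4, K = 30, seed = 2)
  w <- c(0.5, -0.3, 0.2)
  k1 <- exp_kernel(10, support_length = 1)
  expect_equal(reconstruct_trial(x$spikes[, 1, ], w, k1),
               drop(w %*% x$spikes[, 1, ]))
})

test_that("single-trial reconstruction matches the double-sum oracle", {
  x <- random_sts(N = 4, J = 3, K = 120, p = 0.1, seed = 6)
  set.seed(6); w <- rnorm(4)
  k <- exp_kernel(1 / 20)
  for (j in 1:3) {
    got <- reconstruct_trial(x$spikes[, j, ], w, k)
    want <- oracle_reconstruct(x$spikes[, j, ], w, k$values)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # vectorized form agrees with the single-trial form
  M <- reconstruct_trials(x, w, k)
  expect_equal(M[2, ], reconstruct_trial(x$spikes[, 2, ], w, k),
               tolerance = 1e-12)
  # all-zero spikes give an all-zero signal
  expect_equal(reconstruct_trial(matrix(0L, 4, 50), w, k), rep(0, 50))
})

test_that("a single spike produces the weighted kernel as impulse response", {
  spk <- matrix(0L, 2, 60); spk[2, 15] <- 1L
  w <- c(0.3, -0.8)
  k <- exp_kernel(1 / 10)
  got <- reconstruct_trial(spk, w, k)
  expect_equal(got[1:14], rep(0, 14), tolerance = 1e-12)
  L <- min(k$support_length, 60 - 15 + 1)
  expect_equal(got[15:(15 + L - 1)], -0.8 * k$values[1:L],
               tolerance = 1e-12)
})

test_that("reconstruction is linear in the weights", {
  x <- random_sts(N = 5, J = 4, K = 80, seed = 3)
  set.seed(3); w1 <- rnorm(5); w2 <- rnorm(5)
  k <- exp_kernel(1 / 20)
  lhs <- reconstruct_trials(x, 2 * w1 - 0.5 * w2, k)
  rhs <- 2 * reconstruct_trials(x, w1, k) - 0.5 * reconstruct_trials(x, w2, k)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("centering and condition-averaging follow their algebra", {
  # two trials, one per class: difference = a - b, centered = +/-(a-b)/2
  a <- sin(seq(0, 3, length.out = 50)); b <- cos(seq(0, 3, length.out = 50))
  ps <- center_and_average(rbind(b, a), labels = c(-1, 1))
  expect_equal(ps$difference, a - b, tolerance = 1e-12)
  expect_equal(ps$centered[2, ], (a - b) / 2, tolerance = 1e-12)
  expect_equal(ps$centered[1, ], (b - a) / 2, tolerance = 1e-12)
  # equal condition means: difference identically zero
  ps2 <- center_and_average(rbind(a, a, a, a), labels = c(-1, 1, -1, 1))
  expect_equal(ps2$difference, rep(0, 50), tolerance = 1e-12)
  # random input: centered mean is zero at every bin; loop-oracle equality
  set.seed(4)
  M <- matrix(rnorm(8 * 30), 8, 30)
  lab <- rep(c(-1, 1), 4)
  ps3 <- center_and_average(M, lab)
  expect_lt(max(abs(colMeans(ps3$centered))), 1e-10)
  z <- colMeans(M)
  expect_equal(ps3$cond_mean_match,
               colMeans(M[lab == 1, ]) - z, tolerance = 1e-12)
  expect_equal(ps3$difference,
               colMeans(M[lab == 1, ]) - colMeans(M[lab == -1, ]),
               tolerance = 1e-12)
})

test_that("sign split applies the pool-size correction factors", {
  ss <- sign_split(c(0.6, -0.8))
  expect_equal(ss$plus$correction, 1)
  expect_equal(ss$minus$correction, 1)
  ss2 <- sign_split(c(0.5, 0.2, -0.4))
  expect_equal(ss2$plus$correction, 3 / 4)
  expect_equal(ss2$minus$correction, 3 / 2)
  # zero weights belong to neither pool
  ss3 <- sign_split(c(0.5, 0, -0.4))
  expect_equal(ss3$plus$n_sub, 1)
  expect_equal(ss3$minus$n_sub, 1)
  # one-sided weights: the empty side is flagged invalid
  ss4 <- sign_split(c(0.5, 0.1))
  expect_false(ss4$minus$valid)
})

test_that("sign decomposition identity x = x+/f+ + x-/f- holds bin-wise", {
  x <- random_sts(N = 6, J = 8, K = 100, seed = 12)
  set.seed(12)
  w <- rnorm(6); w[w == 0] <- 0.1
  k <- exp_kernel(1 / 20)
  ss <- sign_split(w)
  full <- reconstruct_trials(x, w, k)
  xp <- reconstruct_trials(x, ifelse(ss$plus$mask, w, 0) * ss$plus$correction, k)
  xm <- reconstruct_trials(x, ifelse(ss$minus$mask, w, 0) * ss$minus$correction, k)
  expect_equal(full, xp / ss$plus$correction + xm / ss$minus$correction,
               tolerance = 1e-10)
})

test_that("layer split corrections and the layer decomposition identity", {
  w <- c(0.4, -0.2, 0.3, 0.1, -0.5, 0.2)
  layers <- c("SG", "SG", "G", "G", "IG", "IG")
  ls <- layer_split(w, layers)
  expect_equal(ls$SG$correction, 1)
  expect_equal(ls$G$correction, 1)
  expect_equal(ls$IG$correction, 1)
  all_sg <- layer_split(w, rep("SG", 6))
  expect_equal(all_sg$SG$correction, 1 / 3)
  expect_false(all_sg$G$valid)
  x <- random_sts(N = 6, J = 5, K = 80, seed = 9)
  k <- exp_kernel(1 / 20)
  full <- reconstruct_trials(x, w, k)
  parts <- lapply(ls, function(s)
    reconstruct_trials(x, ifelse(s$mask, w, 0) * s$correction, k) /
      s$correction)
  expect_equal(full, parts$SG + parts$G + parts$IG, tolerance = 1e-10)
})

test_that("subpopulation signals isolate a pool-confined planted effect", {
  # modulation confined to the plus pool; minus neurons carry no effect
  signs <- c(1, 1, 1, 0, 0, 0)
  x <- separable_sts(N = 6, J_per = 60, K = 200, base = 0.05, delta = 0.05,
                     signs = signs, seed = 41)
  w <- c(0.5, 0.5, 0.5, -0.1, -0.1, -0.1)  # plausible learned pattern
  ss <- sign_split(w)
  sp <- subpop_signal(x, w, ss$plus)
  sm <- subpop_signal(x, w, ss$minus)
  expect_gt(mean(sp$difference), 5 * abs(mean(sm$difference)))
  # masking all neurons off gives a flagged all-zero signal
  spec0 <- sign_split(c(-1, -1, -1, -1, -1, -1))$plus
  expect_warning(s0 <- subpop_signal(x, w, spec0), "empty subpopulation")
  expect_false(s0$valid)
  expect_equal(s0$difference, rep(0, 200))
})

test_that("univariate signals depend only on the neuron's own spikes", {
  x <- random_sts(N = 4, J = 10, K = 60, seed = 15)
  cm <- spike_counts_zscored(x)
  aucw <- auc_weights(cm, x$labels)
  k <- exp_kernel(1 / 20)
  sigs <- univariate_signals(x, aucw, k)
  expect_length(sigs, 4)
  # perturb other neurons' spikes: neuron 2's signal is unchanged
  y <- x
  y$spikes[c(1, 3, 4), , ] <- 0L
  sigs2 <- univariate_signals(y, aucw, k)
  expect_equal(sigs2[[2]]$per_trial, sigs[[2]]$per_trial, tolerance = 1e-12)
  # zero weight -> zero signal
  aucw0 <- aucw; aucw0$weights[1] <- 0
  s0 <- univariate_signals(x, aucw0, k)[[1]]
  expect_equal(s0$per_trial, matrix(0, 10, 60))
})

test_that("area-normalized signals agree across kernel time constants", {
  x <- separable_sts(N = 6, J_per = 40, K = 300, delta = 0.04, seed = 51)
  rates <- c(1 / 10, 1 / 20, 1 / 50)
  w <- learn_weights(spike_counts_zscored(x), x$labels, C = 0.1)$weights
  avg <- vapply(rates, function(r) {
    k <- exp_kernel(r, normalized = TRUE)
    sig <- center_and_average(reconstruct_trials(x, w, k), x$labels)
    mean(sig$difference[150:300])  # steady-state part, away from onset
  }, 0.0)
  expect_lt(max(abs(avg - mean(avg))) / abs(mean(avg)), 0.05)
})
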