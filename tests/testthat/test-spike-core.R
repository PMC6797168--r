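test_that("spike_train_set validates its inputs", {
  spk <- array(0L, dim = c(2, 3, 10)); spk[1, 1, 1] <- 1L; spk[2, 3, 5] <- 1L
  x <- spike_train_set(spk, c(-1, 1, 1))
  expect_s3_class(x, "spike_train_set")
  expect_equal(x$n_neurons, 2)
  expect_equal(time_axis(x), 0:9)
  expect_error(spike_train_set(spk, c(1, 1, 1)), "both classes")
  expect_error(spike_train_set(spk, c(-1, 1)), "length")
  spk[1, 1, 1] <- 2L
  expect_error(spike_train_set(spk, c(-1, 1, 1)), "0 or 1")
  expect_error(population_psth(structure(list(), class = "spike_train_set")))
})

test_that("population PSTH handles degenerate and single-spike inputs", {
  zero <- spike_train_set(array(0L, dim = c(2, 2, 50)), c(-1, 1))
  expect_equal(population_psth(zero)$values, rep(0, 50))

  ones <- spike_train_set(array(1L, dim = c(2, 2, 50)), c(-1, 1))
  v <- population_psth(ones)$values
  expect_equal(v[11:40], rep(1, 30), tolerance = 1e-12)  # interior
  expect_true(all(v <= 1 + 1e-12))

  # one spike in an N=2, J=2 set: a bump integrating to 1/(N*J)
  spk <- array(0L, dim = c(2, 2, 50)); spk[1, 2, 25] <- 1L
  p <- population_psth(spike_train_set(spk, c(-1, 1)))
  expect_equal(sum(p$values), 0.25, tolerance = 1e-12)
  expect_equal(sum(p$kernel), 1, tolerance = 1e-12)
})

test_that("smoothed PSTH matches the direct-summation oracle", {
  x <- random_sts(N = 4, J = 6, K = 80, seed = 11)
  p <- population_psth(x)
  expect_equal(p$values, oracle_psth(x$spikes, 10, 10), tolerance = 1e-12)
})

test_that("PSTH of concatenated trial sets is the trial-weighted mean", {
  a <- random_sts(N = 3, J = 4, K = 60, seed = 1)
  b <- random_sts(N = 3, J = 8, K = 60, seed = 2)
  spk <- array(0L, dim = c(3, 12, 60))
  spk[, 1:4, ] <- a$spikes; spk[, 5:12, ] <- b$spikes
  both <- spike_train_set(spk, c(a$labels, b$labels))
  pa <- population_psth(a)$values
  pb <- population_psth(b)$values
  pab <- population_psth(both)$values
  expect_equal(pab, (4 * pa + 8 * pb) / 12, tolerance = 1e-12)
})

test_that("spike counts and z-scores follow the stated conventions", {
  # counts 1, 2, 3 -> z-scores -1, 0, 1 under the sample-variance rule
  spk <- array(0L, dim = c(1, 3, 10))
  spk[1, 1, 1] <- 1L; spk[1, 2, 1:2] <- 1L; spk[1, 3, 1:3] <- 1L
  cm <- spike_counts_zscored(spike_train_set(spk, c(-1, 1, 1)))
  expect_equal(drop(cm$counts), c(1, 2, 3))
  expect_equal(drop(cm$zscores), c(-1, 0, 1))

  # constant counts: zero z-scores plus a warning
  spk2 <- array(0L, dim = c(1, 3, 10)); spk2[1, , 1:5] <- 1L
  expect_warning(
    cm2 <- spike_counts_zscored(spike_train_set(spk2, c(-1, 1, 1))),
    "zero count variance")
  expect_equal(drop(cm2$zscores), c(0, 0, 0))
})

test_that("z-scores match the loop oracle and stats apply across trials", {
  x <- random_sts(N = 3, J = 20, K = 50, seed = 5)
  tr <- 1:10
  cm <- spike_counts_zscored(x, stats_trials = tr)
  expect_equal(cm$zscores, oracle_zscores(cm$counts, tr), tolerance = 1e-12)
  # over the stats trials: mean 0, sample variance 1
  expect_equal(rowMeans(cm$zscores[, tr]), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(cm$zscores[, tr], 1, var), rep(1, 3), tolerance = 1e-10)
})

test_that("counts equal a brute-force per-bin sum and windowing works", {
  x <- random_sts(N = 4, J = 7, K = 40, seed = 9)
  cm <- spike_counts_zscored(x, window = c(10, 30))
  brute <- matrix(0, 4, 7)
  for (n in 1:4) for (j in 1:7) brute[n, j] <- sum(x$spikes[n, j, 11:30])
  expect_equal(unname(cm$counts), brute)
})

test_that("z-scoring is invariant to adding a constant to all counts", {
  set.seed(3)
  counts <- matrix(rpois(60, 8), 3, 20)
  x1 <- oracle_zscores(counts, 1:20)
  x2 <- oracle_zscores(counts + 7, 1:20)
  expect_equal(x1, x2, tolerance = 1e-10)
  # and through the package path: shift every neuron's spikes via extra bins
  x <- random_sts(N = 2, J = 10, K = 30, seed = 2)
  extra <- array(1L, dim = c(2, 10, 5))  # +5 spikes for everyone
  shifted <- spike_train_set(array(c(x$spikes, extra), dim = c(2, 10, 35)),
                             x$labels)
  z1 <- spike_counts_zscored(x)$zscores
  z2 <- spike_counts_zscored(shifted)$zscores
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("plain-text session round-trip preserves everything", {
  x <- random_sts(N = 3, J = 6, K = 25, seed = 8)
  x$depths <- c(100, 500, 900)
  dir <- withr::local_tempdir()
  write_spike_session(x, dir)
  y <- read_spike_session(dir)
  expect_equal(y$spikes, x$spikes)
  expect_equal(y$labels, x$labels)
  expect_equal(y$depths, x$depths)
  expect_equal(y$epoch, x$epoch)
})
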