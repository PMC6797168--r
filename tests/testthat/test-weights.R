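test_that("Monte-Carlo splits are stratified, disjoint and reproducible", {
  lab10 <- rep(c(-1, 1), each = 5)
  s <- monte_carlo_splits(lab10, n_runs = 20, seed = 4)
  expect_length(s, 20)
  for (sp in s) {
    expect_length(sp$train, 5)
    expect_length(sp$valid, 5)
    expect_length(intersect(sp$train, sp$valid), 0)
    expect_setequal(c(sp$train, sp$valid), 1:10)
    expect_true(all(c(-1, 1) %in% lab10[sp$train]))
    expect_true(all(c(-1, 1) %in% lab10[sp$valid]))
  }
  # same seed, same splits; different seed, different splits
  expect_identical(s, monte_carlo_splits(lab10, n_runs = 20, seed = 4))
  expect_false(identical(s, monte_carlo_splits(lab10, n_runs = 20, seed = 5)))

  # odd J: training gets floor(J/2)
  lab11 <- c(rep(-1, 5), rep(1, 6))
  s11 <- monte_carlo_splits(lab11, n_runs = 5, seed = 1)
  for (sp in s11) {
    expect_length(sp$train, 5)
    expect_length(sp$valid, 6)
  }
  expect_error(monte_carlo_splits(c(-1, -1, -1, 1, 1, 1, 1, 1), 1, 1),
               "at least 4")
})

test_that("balanced accuracy follows its defining arithmetic", {
  expect_equal(balanced_accuracy(c(1, 1, -1, -1), c(1, 1, -1, -1)), 1)
  expect_equal(balanced_accuracy(rep(1, 6), rep(c(1, -1), 3)), 0.5)
  # TP=2, FN=0, TN=1, FP=1 -> 0.75
  expect_equal(balanced_accuracy(c(1, 1, -1, 1), c(1, 1, -1, -1)), 0.75)
  expect_error(balanced_accuracy(c(1, 1), c(1, 1)), "both classes")
})

test_that("SVM weights recover a planted single-neuron separation", {
  # classes separated along neuron 1 only: weight concentrates there
  set.seed(2)
  J <- 40
  labels <- rep(c(-1, 1), each = J / 2)
  z <- rbind(labels * 2 + rnorm(J, sd = 0.1), rnorm(J, sd = 0.1))
  wv <- learn_weights(z, labels, C = 1)
  expect_equal(sqrt(sum(wv$weights^2)), 1, tolerance = 1e-10)
  expect_gt(wv$weights[1], 0.99)
  expect_lt(abs(wv$weights[2]), 0.1)
  # brute-force oracle: dense scan of unit directions for the one with the
  # widest class margin; the SVM direction must agree with it
  best <- -Inf; best_th <- NA
  for (th in seq(0, pi, length.out = 2000)) {
    w <- c(cos(th), sin(th))
    proj <- drop(w %*% z)
    m <- (min(proj[labels == 1]) - max(proj[labels == -1])) / 2
    if (m > best) { best <- m; best_th <- th }
  }
  w_best <- c(cos(best_th), sin(best_th))
  expect_gt(abs(sum(w_best * wv$weights)), 0.999)  # same direction
})

test_that("duplicated feature columns get equal weights; norm is 1", {
  set.seed(7)
  labels <- rep(c(-1, 1), each = 15)
  base <- labels + rnorm(30, sd = 0.5)
  z <- rbind(base, base, rnorm(30))
  wv <- learn_weights(z, labels, C = 0.5)
  expect_equal(wv$weights[1], wv$weights[2], tolerance = 1e-6)
  expect_equal(sqrt(sum(wv$weights^2)), 1, tolerance = 1e-10)
})

test_that("positive rescaling of one neuron keeps its weight sign", {
  x <- separable_sts(N = 4, J_per = 25, seed = 13)
  cm <- spike_counts_zscored(x)
  w1 <- learn_weights(cm$zscores, x$labels, C = 0.1)$weights
  z2 <- cm$zscores; z2[2, ] <- 3.5 * z2[2, ]
  w2 <- learn_weights(z2, x$labels, C = 0.1)$weights
  expect_equal(sign(w1[2]), sign(w2[2]))
})

test_that("regularization selection maximizes fold BAC with smallest-C ties", {
  x <- separable_sts(N = 6, J_per = 25, delta = 0.06, seed = 21)
  cm <- spike_counts_zscored(x)
  expect_equal(as.numeric(
    select_regularization(cm, x$labels, grid = 0.05, seed = 1)), 0.05)
  C <- select_regularization(cm, x$labels, seed = 1)
  scores <- attr(C, "scores")
  expect_equal(as.numeric(C),
               as.numeric(names(scores))[which.max(scores)])
  expect_gt(max(scores), 0.95)  # strongly separable data
  # explicit tie: a grid with one value listed twice behaves like one value,
  # and ties between equal-scoring values go to the smaller C
  g <- c(0.1, 0.5)
  s2 <- attr(select_regularization(cm, x$labels, grid = g, seed = 1),
             "scores")
  if (abs(diff(s2)) < 1e-12)
    expect_equal(as.numeric(select_regularization(cm, x$labels, grid = g,
                                                  seed = 1)), 0.1)
})

test_that("AUC weights equal brute-force pair counting and center at chance", {
  set.seed(17)
  J <- 30
  labels <- sample(rep(c(-1, 1), each = J / 2))
  counts <- matrix(rpois(5 * J, 6), 5, J)
  counts[2, labels == 1] <- counts[2, labels == 1] + 20  # perfect separator
  wv <- auc_weights(counts, labels)
  for (n in 1:5)
    expect_equal(wv$auc[n], oracle_auc(counts[n, ], labels))
  expect_equal(wv$auc[2], 1)           # all match counts larger
  centered <- wv$auc - 0.5
  expect_equal(wv$weights, centered / sqrt(sum(centered^2)),
               tolerance = 1e-12)
  # identical distributions -> weight ~ 0
  flat <- matrix(rep(counts[1, ], 2), 2, J, byrow = TRUE)
  wv2 <- auc_weights(flat, labels)
  expect_equal(wv2$auc, rep(wv2$auc[1], 2))
  # constant counts -> AUC 1/2 -> zero weight, no error
  const <- rbind(rep(3, J), counts[2, ])
  wv3 <- auc_weights(const, labels)
  expect_equal(wv3$auc[1], 0.5)
  expect_equal(wv3$weights[1], 0)
})

test_that("label permutation drives validation BAC to chance", {
  x <- separable_sts(N = 5, J_per = 20, delta = 0.05, seed = 31)
  cm <- spike_counts_zscored(x)
  sp <- monte_carlo_splits(x$labels, 1, seed = 2)[[1]]
  set.seed(99)
  bacs <- replicate(100, {
    p <- sample(x$labels)
    wv <- learn_weights(cm$zscores[, sp$train], p[sp$train], C = 0.1)
    f <- drop(wv$weights %*% cm$zscores[, sp$valid]) + wv$offset_norm
    balanced_accuracy(ifelse(f > 0, 1, -1), p[sp$valid])
  })
  expect_gt(mean(bacs), 0.45)
  expect_lt(mean(bacs), 0.55)
})
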