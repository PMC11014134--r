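test_that("LDA separates well-separated Gaussians near the Bayes rate", {
  set.seed(31)
  d <- 6; n <- 200
  x <- rbind(matrix(rnorm(n * d, 5), n, d), matrix(rnorm(n * d, -5), n, d))
  y <- rep(c("a", "b"), each = n)
  hold <- sample(2 * n, 80)
  fit <- lda_fit(x[-hold, ], y[-hold])
  expect_gt(mean(lda_predict(fit, x[hold, ]) == y[hold]), 0.99)
})

test_that("identical class distributions give chance-level accuracy", {
  set.seed(5)
  x <- matrix(rnorm(900), 300, 3)
  y <- rep(c("a", "b", "c"), 100)
  hold <- 201:300
  fit <- lda_fit(x[-hold, ], y[-hold])
  acc <- mean(lda_predict(fit, x[hold, ]) == y[hold])
  expect_lt(abs(acc - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 100)) # binomial noise
})

test_that("fitting is deterministic and closed-form properties hold", {
  set.seed(2)
  x <- matrix(rnorm(120), 40, 3)
  y <- rep(c("p", "q"), 20)
  f1 <- lda_fit(x, y)
  f2 <- lda_fit(x, y)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$cov, f2$cov)
  expect_equal(sum(f1$priors), 1)
  expect_true(all(eigen(f1$cov, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(lda_fit(x, rep("one", 40)), "2 classes")
  expect_error(lda_predict(f1, x[, 1:2]), "dimension")
})

test_that("prediction respects means, priors and deterministic tie-break", {
  means <- rbind(a = c(0, 0), b = c(4, 4))
  set.seed(8)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  fit <- lda_fit(x, y)
  # a point exactly at a class's fitted mean goes to that class
  expect_equal(lda_predict(fit, fit$means["a", , drop = FALSE]), "a")
  expect_equal(lda_predict(fit, fit$means["b", , drop = FALSE]), "b")
  # equidistant point with unequal priors goes to the higher-prior class
  x2 <- rbind(x, matrix(rnorm(40, 4), 20, 2))
  y2 <- c(y, rep("b", 20))
  fit2 <- lda_fit(x2, y2)
  mid <- (fit2$means["a", ] + fit2$means["b", ]) / 2
  sc <- lda_predict(fit2, matrix(mid, 1), scores = TRUE)
  # remove the prior term: the remaining scores tie at the midpoint
  expect_equal(unname(sc[1, "b"] - sc[1, "a"]),
               log(fit2$priors[2]) - log(fit2$priors[1]), tolerance = 1e-6)
})

test_that("predictions are invariant under a common affine feature map", {
  set.seed(77)
  x <- rbind(matrix(rnorm(150, 0), 50, 3), matrix(rnorm(150, 2), 50, 3))
  y <- rep(c("a", "b"), each = 50)
  xt <- matrix(rnorm(60), 20, 3)
  A <- matrix(c(2, 0.3, 0, -0.5, 1.5, 0.2, 0.1, 0, 3), 3, 3)
  b <- c(5, -2, 1)
  f0 <- lda_fit(x, y, lambda = 0)
  f1 <- lda_fit(sweep(x %*% A, 2, b, "+"), y, lambda = 0)
  expect_equal(lda_predict(f0, xt),
               lda_predict(f1, sweep(xt %*% A, 2, b, "+")))
})

test_that("closed-form LDA agrees with the reference implementation", {
  set.seed(14)
  x <- rbind(matrix(rnorm(240, 0), 80, 3),
             matrix(rnorm(240, 1.2), 80, 3),
             matrix(rnorm(240, -1), 80, 3))
  y <- rep(c("a", "b", "c"), each = 80)
  xt <- matrix(rnorm(150), 50, 3)
  ours <- lda_predict(lda_fit(x, y, lambda = 0), xt)
  ref <- as.character(predict(MASS::lda(x, grouping = y), xt)$class)
  expect_equal(ours, ref)
})

test_that("TDF features + LDA exceed chance by 3x on the synthetic motions", {
  cfg <- simulation_config(stim_amplitude_ratio = 0, seed = 6)
  mk <- function(motion, s) {
    rec <- generate_recording(cfg, motion, "no_fatigue", 0.5, seed = s)
    lapply(1:4, function(ch) signal_window(rec$samples[ch, ], ch, 8000, 0,
                                           motion, "no_fatigue"))
  }
  examples <- list(); labels <- c()
  for (m in motion_labels()) for (s in 1:12) {
    examples[[length(examples) + 1]] <- mk(m, s)
    labels <- c(labels, m)
  }
  feats <- example_feature_matrix(examples, "tdf", wl_form = "conventional")
  test_ix <- seq(4, length(labels), by = 4)
  fit <- lda_fit(feats[-test_ix, ], labels[-test_ix])
  acc <- mean(lda_predict(fit, feats[test_ix, , drop = FALSE]) == labels[test_ix])
  expect_gt(acc, 3 / 6)
})
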