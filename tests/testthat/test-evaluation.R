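test_that("counts confusion matrices behave like counts", {
  y <- rep(c("a", "b", "c"), each = 4)
  cm <- confusion_from_predictions(y, y)
  expect_true(all(cm$matrix[upper.tri(cm$matrix)] == 0))
  expect_true(all(cm$matrix[lower.tri(cm$matrix)] == 0))
  expect_equal(sum(cm$matrix), 12)

  # swapping two predictions moves exactly two units of mass
  y2 <- y; y2[c(1, 5)] <- c("b", "a")
  cm2 <- confusion_from_predictions(y, y2)
  expect_equal(sum(abs(cm2$matrix - cm$matrix)), 4) # 2 moved + 2 removed
  expect_equal(sum(cm2$matrix), 12)

  expect_error(confusion_from_predictions(y, y[-1]), "equal length")
  expect_error(confusion_from_predictions(y, y, labels = c("a", "b")),
               "labels")
})

test_that("metrics from counts match hand arithmetic and a brute-force oracle", {
  # identity matrix: everything 100%
  ident <- confusion_from_predictions(rep(c("x", "y", "z"), each = 10),
                                      rep(c("x", "y", "z"), each = 10))
  mi <- metrics_from_counts(ident)
  expect_equal(mi$precision, rep(100, 3))
  expect_equal(mi$recall, rep(100, 3))
  expect_equal(mi$f1, rep(100, 3))
  expect_equal(overall_accuracy(mi), 100)

  # hand-computed 2x2: [[8,2],[3,7]]
  yt <- c(rep("a", 10), rep("b", 10))
  yp <- c(rep("a", 8), rep("b", 2), rep("a", 3), rep("b", 7))
  m <- metrics_from_counts(confusion_from_predictions(yt, yp))
  expect_equal(m$precision[1], 8 / 11 * 100, tolerance = 1e-10)
  expect_equal(m$recall[1], 80)
  expect_equal(overall_accuracy(m), 75)

  # random 6x6 matrices: accuracy equals the brute-force match count
  set.seed(12)
  for (i in 1:20) {
    cnt <- matrix(rpois(36, 5), 6, 6)
    labels <- letters[1:6]
    yt <- rep(rep(labels, times = rowSums(cnt)))
    yp <- unlist(lapply(1:6, function(r) rep(labels, times = cnt[r, ])))
    cm <- confusion_from_predictions(yt, yp, labels = labels)
    expect_equal(overall_accuracy(metrics_from_counts(cm)),
                 mean(yt == yp) * 100, tolerance = 1e-10)
  }
})

test_that("normalized-matrix metrics agree with counts on balanced data", {
  set.seed(4)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    cnt <- matrix(0, k, k)
    for (r in 1:k) {
      cnt[r, ] <- rmultinom(1, 1000, prob = runif(k) + (1:k == r) * 3)
    }
    labels <- letters[1:k]
    cm <- structure(list(matrix = cnt, labels = labels, normalized = FALSE),
                    class = "fessemg_confusion")
    m1 <- metrics_from_counts(cm)
    m2 <- metrics_from_normalized(normalize_confusion(cm))
    expect_equal(m1$precision, m2$precision, tolerance = 1e-4)
    expect_equal(m1$recall, m2$recall, tolerance = 1e-4)
    expect_equal(m1$f1, m2$f1, tolerance = 1e-4)
    expect_equal(overall_accuracy(m1), overall_accuracy(m2), tolerance = 1e-4)
  }
})

test_that("F1 lies between precision and recall; accuracy is permutation-invariant", {
  set.seed(99)
  cnt <- matrix(rpois(36, 8) + 1, 6, 6)
  cm <- structure(list(matrix = cnt, labels = letters[1:6], normalized = FALSE),
                  class = "fessemg_confusion")
  m <- metrics_from_counts(cm)
  expect_true(all(pmin(m$precision, m$recall) <= m$f1 + 1e-9))
  expect_true(all(m$f1 <= pmax(m$precision, m$recall) + 1e-9))

  perm <- sample(6)
  cmp <- structure(list(matrix = cnt[perm, perm], labels = letters[1:6][perm],
                        normalized = FALSE), class = "fessemg_confusion")
  expect_equal(overall_accuracy(metrics_from_counts(cmp)),
               overall_accuracy(metrics_from_counts(cm)))
})

test_that("published matrices load with sane row sums and printed values intact", {
  for (nm in c("hht_net_motion", "tdf_lda_motion")) {
    cm <- published_confusion(nm)
    expect_true(cm$normalized)
    expect_equal(cm$labels, motion_labels())
    expect_true(all(abs(rowSums(cm$matrix) - 100) <= 0.5))
  }
  # identity percentage matrix: all metrics 100
  eye <- confusion_from_normalized(diag(100, 4), labels = letters[1:4])
  me <- metrics_from_normalized(eye)
  expect_equal(me$f1, rep(100, 4))
  expect_equal(overall_accuracy(me), 100)
  # malformed row sums rejected
  expect_error(confusion_from_normalized(matrix(c(60, 20, 30, 70), 2, 2)),
               "row sums")
})
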