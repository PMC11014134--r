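test_that("shape table reproduces the published architecture contract", {
  cfg <- model_config() # full-scale defaults
  sh <- model_shapes(cfg)
  expect_equal(attr(sh, "concat_dim"), 16 * 16 * 20 * 4) # 20,480
  expect_equal(attr(sh, "fatigue_concat_dim"), 4 * 1024) # 4,096
  expect_equal(sh$output[sh$layer == "FC2" & sh$module == "motion"], "6")
  expect_equal(sh$output[sh$layer == "FC2" & sh$module == "fatigue"], "3")
  # documented dimension corrections: fatigue FC pair composes 4096->512->3
  expect_equal(sh$input[sh$layer == "FC1" & sh$module == "fatigue"], "4096")
  expect_equal(sh$output[sh$layer == "FC1" & sh$module == "fatigue"], "512")
  # rows_as_steps default: 16 steps x 320 features per branch
  expect_equal(sh$input[sh$layer == "LSTM1"], "16 steps x 320")
  expect_error(model_config(input_shape = c(100, 100, 3)), "divisible by 16")
  expect_error(model_config(fatigue_fc_dims = c(512, 4)), "fatigue_classes")
})

test_that("forward pass emits simplex outputs of the right shape", {
  cfg <- fx_tiny_model_config()
  m <- build_model(cfg)
  set.seed(1)
  ex <- lapply(1:2, function(i) labeled_example(
    lapply(1:4, function(b) array(runif(16 * 16 * 3), c(16, 16, 3))),
    motion_labels()[i], fatigue_labels()[i]))
  pr <- predict(m, ex)
  expect_equal(dim(pr$motion_probs), c(2L, 6L))
  expect_equal(dim(pr$fatigue_probs), c(2L, 3L))
  expect_equal(rowSums(pr$motion_probs), c(1, 1), tolerance = 1e-6)
  expect_equal(rowSums(pr$fatigue_probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(pr$motion_probs >= 0))
  # eval-mode repeatability
  pr2 <- predict(m, ex)
  expect_identical(pr$motion_probs, pr2$motion_probs)
  # mismatched image size rejected
  bad <- labeled_example(lapply(1:4, function(b) array(0, c(32, 32, 3))),
                         "sitting", "no_fatigue")
  expect_error(predict(m, list(bad)), "expected")
})

test_that("dual loss satisfies its closed forms and additivity", {
  onehot <- function(k, i) { v <- numeric(k); v[i] <- 1; v }
  expect_equal(dual_loss(onehot(6, 2), 2, onehot(3, 3), 3), 0)
  expect_equal(dual_loss(rep(1 / 6, 6), 4, rep(1 / 3, 3), 1),
               log(6) + log(3))
  expect_equal(log(6) + log(3), 2.8904, tolerance = 1e-4)
  # additivity against single-task cross-entropies on random cases
  set.seed(20)
  for (i in 1:50) {
    mp <- runif(6); mp <- mp / sum(mp)
    fp <- runif(3); fp <- fp / sum(fp)
    ml <- sample(6, 1); fl <- sample(3, 1)
    expect_equal(dual_loss(mp, ml, fp, fl),
                 -log(mp[ml]) - log(fp[fl]), tolerance = 1e-12)
  }
  expect_error(dual_loss(rep(1 / 6, 6), 7, rep(1 / 3, 3), 1), "label")
})

test_that("stratified splitting is exact, disjoint, exhaustive and seeded", {
  ex <- fx_separable_examples(reps = 6) # 108 examples, 18 strata of 6
  sp <- split_dataset(ex[1:100], fractions = c(0.8, 0.1, 0.1), seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  all_ix <- c(sp$indices$train, sp$indices$val, sp$indices$test)
  expect_equal(sort(all_ix), 1:100)
  sp2 <- split_dataset(ex[1:100], fractions = c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(sp$indices, sp2$indices)
  sp3 <- split_dataset(ex[1:100], fractions = c(0.8, 0.1, 0.1), seed = 5)
  expect_false(identical(sp$indices, sp3$indices))
  expect_warning(split_dataset(ex[1:8], seed = 1), "stratum")
  expect_error(split_dataset(ex, fractions = c(0.9, 0.2, 0.1)), "sum to 1")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- fx_tiny_model_config(seed = 3)
  m <- build_model(cfg)
  set.seed(10)
  ex <- lapply(1:3, function(i) labeled_example(
    lapply(1:4, function(b) array(runif(16 * 16 * 3), c(16, 16, 3))),
    motion_labels()[i], fatigue_labels()[(i - 1) %% 3 + 1]))
  pk <- fessemg:::pack_examples(ex, cfg)
  fessemg:::.net_backward(m$ptr, pk$X, pk$motion, pk$fatigue)
  gr <- fessemg:::.net_get_grads(m$ptr)
  pa <- fessemg:::.net_get_params(m$ptr)
  eps <- 1e-5
  set.seed(42)
  for (pi in sample(seq_along(pa), 10)) {
    el <- sample(length(pa[[pi]]), 1)
    loss_at <- function(v) {
      p2 <- pa
      p2[[pi]][el] <- v
      fessemg:::.net_set_params(m$ptr, p2)
      fessemg:::.net_loss(m$ptr, pk$X, pk$motion, pk$fatigue, TRUE)$loss
    }
    num <- (loss_at(pa[[pi]][el] + eps) - loss_at(pa[[pi]][el] - eps)) / (2 * eps)
    ana <- gr[[pi]][el]
    expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
  }
})

test_that("training memorizes trivially separable images and descends from uniform", {
  ex <- fx_separable_examples(reps = 3)
  m <- build_model(fx_tiny_model_config(seed = 2))
  tc <- train_config(epochs = 20, batch_size = 6, learning_rate = 0.003,
                     seed = 9)
  m <- train_model(m, ex, ex, tc)
  expect_lte(m$history$train_loss[1], log(6) + log(3) + 0.2)
  pr <- predict(m, ex)
  tm <- vapply(ex, function(e) e$motion_label, character(1))
  tf <- vapply(ex, function(e) e$fatigue_label, character(1))
  expect_equal(mean(pr$motion == tm), 1)
  expect_equal(mean(pr$fatigue == tf), 1)
  expect_equal(nrow(m$history), 20)
  expect_true(all(is.finite(m$history$train_loss)))

  # same seeds -> identical epoch-1 losses (pipeline determinism)
  m2 <- build_model(fx_tiny_model_config(seed = 2))
  m2 <- train_model(m2, ex, ex, train_config(epochs = 1, batch_size = 6,
                                             learning_rate = 0.003, seed = 9))
  expect_equal(m2$history$train_loss[1], m$history$train_loss[1])
})

test_that("checkpoint round-trip preserves predictions", {
  ex <- fx_separable_examples(reps = 1)
  m <- build_model(fx_tiny_model_config(seed = 6))
  m <- train_model(m, ex, ex, train_config(epochs = 2, batch_size = 6, seed = 1))
  p1 <- predict(m, ex)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  p2 <- predict(m2, ex)
  expect_equal(p1$motion_probs, p2$motion_probs, tolerance = 1e-12)
  expect_equal(p1$fatigue_probs, p2$fatigue_probs, tolerance = 1e-12)
  unlink(f)
})
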