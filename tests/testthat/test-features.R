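test_that("time-domain features match hand computations", {
  x <- c(1, -1, 1, -1)
  f <- tdf_features(x, epsilon = 0)
  expect_equal(unname(f["MAV"]), 1)
  expect_equal(unname(f["ZC"]), 3)

  const <- tdf_features(rep(2.5, 100))
  expect_equal(unname(const[c("WL", "ZC", "SSC")]), c(0, 0, 0))

  ramp <- tdf_features(seq(1, 10, length.out = 50))
  expect_equal(unname(ramp[c("ZC", "SSC")]), c(0, 0))

  # printed WL telescopes; conventional sums absolute differences
  y <- c(0, 3, -1, 4)
  expect_equal(unname(tdf_features(y, wl_form = "printed")["WL"]),
               (4 - 0) / 4)
  expect_equal(unname(tdf_features(y, wl_form = "conventional")["WL"]),
               3 + 4 + 5)

  # the epsilon gate suppresses small crossings
  small <- c(0.1, -0.1, 0.1, -0.1)
  expect_equal(unname(tdf_features(small, epsilon = 0.5)["ZC"]), 0)
  expect_error(tdf_features(numeric(0)), "empty")
  expect_error(tdf_features(x, epsilon = -1), "epsilon")
})

test_that("spectral fatigue features match closed forms and the generator", {
  f <- tff_features(c(3, -4), fs = 8000)
  expect_equal(unname(f["RMS"]), sqrt(12.5))
  expect_equal(unname(f["iEMG"]), 7)

  tone <- fx_tone(100)
  ft <- tff_features(tone)
  p <- welch_psd(tone$samples, 8000, nperseg = 1024)
  bin <- diff(p$freq[1:2])
  expect_lt(abs(ft[["MF"]] - 100), bin)
  expect_lt(abs(ft[["MPF"]] - 100), bin)

  z <- tff_features(numeric(100), fs = 8000)
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_equal(unname(z[c("MF", "MPF")]), c(0, 0))

  # generator link: extreme-fatigue windows have lower mean MF (10 seeds)
  cfg <- fx_simconfig()
  mf_of <- function(fatigue) mean(sapply(1:10, function(s) {
    rec <- generate_recording(cfg, "cycling", fatigue, 0.5, seed = s)
    tff_features(signal_window(rec$clean[1, ], 1L, 8000))[["MF"]]
  }))
  expect_lt(mf_of("extreme"), mf_of("no_fatigue"))
})

test_that("feature scaling behaves as defined", {
  set.seed(9)
  x <- rnorm(500)
  f1 <- tdf_features(x)
  f2 <- tdf_features(3 * x)
  expect_equal(unname(f2["MAV"]), 3 * unname(f1["MAV"]))
  # with epsilon = 0, ZC and SSC are amplitude-invariant
  expect_equal(unname(f2[c("ZC", "SSC")]), unname(f1[c("ZC", "SSC")]))
  g1 <- tff_features(x, fs = 8000)
  g2 <- tff_features(3 * x, fs = 8000)
  expect_equal(unname(g2[c("RMS", "iEMG")]), 3 * unname(g1[c("RMS", "iEMG")]))
  expect_equal(unname(g2[c("MF", "MPF")]), unname(g1[c("MF", "MPF")]))
})

test_that("epsilon selection sweeps R and returns the validation best", {
  expect_equal(epsilon_from_rest(c(3, -4), 2), 2 * sqrt(12.5))
  cfg <- fx_simconfig()
  mk_ex <- function(motion, s) {
    rec <- generate_recording(cfg, motion, "no_fatigue", 0.5, seed = s)
    lapply(1:2, function(ch) signal_window(rec$clean[ch, ], ch, 8000, 0,
                                           motion, "no_fatigue"))
  }
  train <- c(lapply(1:6, function(s) mk_ex("sitting", s)),
             lapply(1:6, function(s) mk_ex("walking", s)))
  val <- c(lapply(7:9, function(s) mk_ex("sitting", s)),
           lapply(7:9, function(s) mk_ex("walking", s)))
  lab_tr <- rep(c("sitting", "walking"), each = 6)
  lab_va <- rep(c("sitting", "walking"), each = 3)
  sel <- select_zc_epsilon(train, lab_tr, val, lab_va, rest_rms = 0.1,
                           r_grid = c(0, 1, 3))
  expect_true(sel$R %in% c(0, 1, 3))
  expect_equal(sel$epsilon, sel$R * 0.1)
  expect_gte(sel$val_accuracy, 0.5)
})

test_that("feature matrices concatenate channels with labels preserved", {
  cfg <- fx_simconfig()
  rec <- generate_recording(cfg, "walking", "medium", 0.5, seed = 2)
  ex <- lapply(1:4, function(ch) signal_window(rec$samples[ch, ], ch, 8000, 0,
                                               "walking", "medium"))
  m <- example_feature_matrix(list(ex), "tdf")
  expect_equal(dim(m), c(1L, 16L))
  expect_true(all(grepl("^ch[1-4]_(MAV|WL|ZC|SSC)$", colnames(m))))
  m2 <- example_feature_matrix(list(ex), "tff")
  expect_true(all(grepl("^ch[1-4]_(RMS|iEMG|MF|MPF)$", colnames(m2))))
  expect_true(all(is.finite(m)), all(is.finite(m2)))
})
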