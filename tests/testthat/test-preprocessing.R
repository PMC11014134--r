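test_that("segmentation produces the stride-arithmetic window counts", {
  cfg <- fx_simconfig()
  rec <- generate_recording(cfg, "walking", "no_fatigue", 2)
  w0 <- segment(rec, 0.5, 0)
  expect_length(w0, 4 * 4) # 4 windows x 4 channels
  w5 <- segment(rec, 0.5, 0.5)
  expect_length(w5, 7 * 4) # (2 - 0.5)/0.25 + 1 = 7 per channel
  # every window: 4000 samples at 8 kHz, labels copied
  for (w in w5[c(1, 10, 28)]) {
    expect_length(w$samples, 4000)
    expect_equal(w$sampling_rate_hz, 8000)
    expect_equal(w$motion_label, "walking")
    expect_equal(w$fatigue_label, "no_fatigue")
  }
  expect_error(segment(generate_recording(cfg, "walking", "no_fatigue", 0.6), 1.0),
               "longer than recording")
  expect_error(segment(rec, 0.5, 1), "overlap_fraction")
})

test_that("EMD handles monotone input, separates tones, and is complete", {
  # monotone ramp: no extrema, zero IMFs, residue = input
  ramp <- seq(0, 1, length.out = 200)
  e <- emd(ramp)
  expect_equal(n_imfs(e), 0)
  expect_equal(e$residue, ramp)

  # two-tone separation: IMF1 tracks the fast component
  fs <- 8000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 30 * t) + sin(2 * pi * 2 * t)
  e2 <- emd(x)
  core <- seq(0.1 * length(t), 0.9 * length(t))
  expect_gt(cor(e2$imfs[core, 1], sin(2 * pi * 30 * t)[core]), 0.95)

  # completeness within 1e-8 x RMS on random seeded signals
  set.seed(42)
  for (i in 1:20) {
    y <- cumsum(rnorm(500)) + sin(2 * pi * (1:500) / runif(1, 10, 100))
    d <- emd(y)
    recon <- d$residue + if (n_imfs(d)) rowSums(d$imfs) else 0
    expect_lt(max(abs(recon - y)), 1e-8 * sqrt(mean(y^2)))
  }

  expect_error(emd(c(1, 2, NA, 4, 5, 6, 7, 8)), "non-finite")
  expect_error(emd(1:5), "length")
})

test_that("IMFs are ordered from high to low characteristic frequency", {
  w <- fx_window("walking", "medium", seed = 7)
  d <- emd(w$samples)
  cents <- sapply(seq_len(n_imfs(d)), function(j) {
    p <- welch_psd(d$imfs[, j], 8000, nperseg = 2048)
    mean_power_frequency(p$freq, p$psd)
  })
  expect_true(all(diff(cents) < 0))
})

test_that("artifact removal preserves structure and suppresses stimulation lines", {
  # zero in, zero out; length/labels/channel preserved
  z <- signal_window(numeric(4000), 2L, 8000, 0.5, "walking", "medium")
  zc <- remove_fes_artifacts(z)
  expect_identical(zc$samples, z$samples)
  w <- fx_window("cycling", "no_fatigue", seed = 4)
  wc <- remove_fes_artifacts(w)
  expect_length(wc$samples, 4000)
  expect_equal(wc$channel_id, w$channel_id)
  expect_equal(wc$motion_label, w$motion_label)
  expect_equal(wc$fatigue_label, w$fatigue_label)
  expect_error(remove_fes_artifacts(w, stim_freq_hz = 1500, n_harmonics = 5),
               "Nyquist")

  # >= 20 dB suppression of the 20/40/60 Hz stimulation lines (3 seeds)
  for (s in 4:6) {
    w <- fx_window("cycling", "no_fatigue", seed = s)
    wc <- remove_fes_artifacts(w)
    for (f0 in c(20, 40, 60)) {
      drop_db <- band_power_db(w$samples, 8000, f0) -
        band_power_db(wc$samples, 8000, f0)
      expect_gt(drop_db, 20)
    }
  }

  # <= 10% RMS distortion on artifact-free windows (3 seeds)
  for (s in 4:6) {
    w0 <- fx_window("walking", "no_fatigue", seed = s, clean = TRUE)
    wc0 <- remove_fes_artifacts(w0)
    expect_lt(abs(sqrt(mean(wc0$samples^2)) / sqrt(mean(w0$samples^2)) - 1),
              0.10)
  }
})

test_that("artifact removal moves the signal toward the ground-truth clean signal", {
  cfg <- fx_simconfig()
  gains <- sapply(1:10, function(s) {
    rec <- generate_recording(cfg, "walking", "medium", 0.5, seed = s)
    w <- segment(rec, 0.5, 0)[[1]]
    wc <- remove_fes_artifacts(w)
    cor(wc$samples, rec$clean[1, ]) - cor(w$samples, rec$clean[1, ])
  })
  expect_gt(mean(gains), 0)
})
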