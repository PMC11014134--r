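test_that("recordings are deterministic by seed and carry the right shape", {
  cfg <- fx_simconfig()
  r1 <- generate_recording(cfg, "sitting", "no_fatigue", 2)
  r2 <- generate_recording(cfg, "sitting", "no_fatigue", 2)
  expect_identical(r1$samples, r2$samples)
  expect_equal(dim(r1$samples), c(4L, 16000L))
  expect_equal(r1$motion_label, "sitting")
  expect_equal(r1$fatigue_label, "no_fatigue")
  r3 <- generate_recording(cfg, "sitting", "no_fatigue", 2, seed = 99)
  expect_false(identical(r1$samples, r3$samples))
  # duration x rate = columns within one sample
  r4 <- generate_recording(cfg, "walking", "medium", 0.7501)
  expect_lte(abs(ncol(r4$samples) - 0.7501 * 8000), 1)
})

test_that("label and duration validation raises labeled errors", {
  cfg <- fx_simconfig()
  expect_error(generate_recording(cfg, "jogging", "no_fatigue", 1),
               "unknown motion")
  expect_error(generate_recording(cfg, "walking", "tired", 1),
               "unknown fatigue")
  expect_error(generate_recording(cfg, "walking", "no_fatigue", 0.2),
               "duration")
})

test_that("config invariants on the fatigue maps are enforced", {
  expect_error(simulation_config(
    fatigue_spectral_scale = c(no_fatigue = 0.8, medium = 0.85, extreme = 0.7)),
    "strictly decreasing")
  expect_error(simulation_config(
    fatigue_amplitude_gain = c(no_fatigue = 1.2, medium = 1.1, extreme = 1.3)),
    "non-decreasing")
  expect_error(simulation_config(motion_envelopes = list(sitting = NULL)),
               "every motion label")
})

test_that("stimulation artifact imprints harmonic lines; disabling it removes them", {
  w <- fx_window("cycling", "no_fatigue", seed = 11)
  p <- welch_psd(w$samples, 8000, nperseg = 4000)
  for (k in 1:5) {
    f0 <- 20 * k
    line <- sum(p$psd[abs(p$freq - f0) <= 1])
    cont <- stats::median(p$psd[abs(p$freq - f0) <= 9 & abs(p$freq - f0) > 2])
    expect_gt(line / cont, 2)
  }
  # with the artifact disabled the expected spectrum has no line component;
  # average the PSD over realizations so the single-window chi-squared
  # fluctuation does not mimic a line
  cfg0 <- simulation_config(stim_amplitude_ratio = 0, noise_rms = 0, seed = 3)
  psd0 <- NULL
  for (s in 10:15) {
    r <- generate_recording(cfg0, "cycling", "no_fatigue", 0.5, seed = s)
    p0 <- welch_psd(r$samples[1, ], 8000, nperseg = 1024)
    psd0 <- if (is.null(psd0)) p0$psd else psd0 + p0$psd
  }
  ratios <- sapply(1:5, function(k) {
    f0 <- 20 * k
    mean(psd0[abs(p0$freq - f0) <= 4]) /
      stats::median(psd0[abs(p0$freq - f0) <= 40 & abs(p0$freq - f0) > 4])
  })
  expect_true(all(ratios < 2))
})

test_that("fatigue compresses the spectrum and raises amplitude, monotonically", {
  cfg <- fx_simconfig()
  stats_for <- function(motion, fatigue) {
    vals <- sapply(1:10, function(s) {
      rec <- generate_recording(cfg, motion, fatigue, 0.5, seed = s)
      p <- welch_psd(rec$clean[1, ], 8000)
      c(mf = median_frequency(p$freq, p$psd), rms = sqrt(mean(rec$clean^2)))
    })
    rowMeans(vals)
  }
  for (motion in c("cycling", "ankle_dorsiflexion")) {
    s_no <- stats_for(motion, "no_fatigue")
    s_md <- stats_for(motion, "medium")
    s_ex <- stats_for(motion, "extreme")
    expect_gt(s_no["mf"], s_md["mf"])
    expect_gt(s_md["mf"], s_ex["mf"])
    expect_lt(s_no["rms"], s_md["rms"])
    expect_lt(s_md["rms"], s_ex["rms"])
  }
})

test_that("generate_dataset balances classes and is seed-deterministic", {
  cfg <- fx_simconfig()
  recs <- generate_dataset(cfg, 10)
  expect_length(recs, 60)
  man <- attr(recs, "manifest")
  expect_equal(unname(table(man$motion)[motion_labels()]),
               rep(10L, 6), ignore_attr = TRUE)
  # daily tasks carry no_fatigue only
  daily <- man$motion %in% c("sitting", "walking", "climbing_stairs")
  expect_true(all(man$fatigue[daily] == "no_fatigue"))
  # rehab motions cycle uniformly through fatigue levels when divisible by 3
  recs9 <- generate_dataset(cfg, 9)
  man9 <- attr(recs9, "manifest")
  cyc <- man9$fatigue[man9$motion == "cycling"]
  expect_equal(unname(table(cyc)[fatigue_labels()]), rep(3L, 3),
               ignore_attr = TRUE)
  # determinism: same config -> same labels and first recording
  recs_b <- generate_dataset(cfg, 10)
  expect_identical(attr(recs_b, "manifest"), man)
  expect_identical(recs_b[[1]]$samples, recs[[1]]$samples)
})

test_that("per-channel MAV patterns separate the motions", {
  cfg <- fx_simconfig()
  mav <- function(motion, s) {
    rec <- generate_recording(cfg, motion, "no_fatigue", 0.5, seed = s)
    rowMeans(abs(rec$clean))
  }
  mus <- sapply(motion_labels(), function(m)
    rowMeans(sapply(1:8, function(s) mav(m, s))))
  d <- as.matrix(dist(t(mus)))
  # every pair of motion class-mean MAV vectors differs by a margin
  expect_gt(min(d[upper.tri(d)]), 0.02)
})
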