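test_that("STFT localizes tones, zeroes vanish, and Parseval holds", {
  tone <- fx_tone(100)
  sp <- stft_spectrogram(tone)
  prof <- rowMeans(sp$power)
  expect_equal(sp$freq_axis[which.max(prof)],
               sp$freq_axis[which.min(abs(sp$freq_axis - 100))])

  z <- signal_window(numeric(4000), 1L, 8000)
  expect_true(all(stft_spectrogram(z)$power == 0))

  expect_error(stft_spectrogram(tone, taper = "kaiser"), "taper")

  # Parseval with a COLA-compliant hop: signal supported away from the
  # edges so every sample is covered by the full taper overlap
  n <- 4000; wlen <- 256; hop <- 64
  x <- numeric(n)
  core <- (wlen + 1):(n - wlen)
  set.seed(7)
  x[core] <- rnorm(length(core))
  w <- signal_window(x, 1L, 8000)
  sp2 <- stft_spectrogram(w, fft_window_len = wlen, hop = hop)
  taper <- hann_taper(wlen)
  # overlap constant of the squared taper, computed from the taper itself
  C <- sum(taper^2) / hop
  expect_equal(sum(sp2$power), wlen * C * sum(x^2), tolerance = 1e-6)
})

test_that("bump-wavelet scalogram finds ridges and is |.|^2-homogeneous", {
  tone <- fx_tone(150)
  sc <- cwt_scalogram(tone)
  ridge <- which.max(rowMeans(sc$power))
  step <- sc$freq_axis[2] / sc$freq_axis[1] # log spacing ratio
  expect_lt(abs(log(sc$freq_axis[ridge] / 150)), log(step) * 1.5)

  sc2 <- cwt_scalogram(fx_tone(150, amp = 2))
  expect_equal(sc2$power, 4 * sc$power, tolerance = 1e-9)

  # two tones -> two ridges at matching center frequencies
  t <- (0:3999) / 8000
  two <- signal_window(sin(2 * pi * 60 * t) + sin(2 * pi * 200 * t), 1L, 8000)
  sc3 <- cwt_scalogram(two)
  prof <- rowMeans(sc3$power)
  peaks <- which(diff(sign(diff(prof))) == -2) + 1
  peak_freqs <- sc3$freq_axis[peaks[order(prof[peaks], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(log(peak_freqs / 60))), log(step) * 1.5)
  expect_lt(min(abs(log(peak_freqs / 200))), log(step) * 1.5)

  expect_error(cwt_scalogram(tone, freq_range_hz = c(100, 5000)), "Nyquist|range")
})

test_that("Hilbert spectrum recovers tone amplitude/frequency and chirp ridges", {
  fs <- 8000; n <- 4000
  t <- (seq_len(n) - 1) / fs
  tone <- 0.7 * sin(2 * pi * 100 * t)
  imfset <- structure(list(imfs = matrix(tone, ncol = 1), residue = numeric(n)),
                      class = "fessemg_imfset")
  # analytic amplitude ~ 0.7 away from edges
  a <- Mod(hilbert_analytic(tone))
  core <- seq(0.1 * n, 0.9 * n)
  expect_lt(max(abs(a[core] - 0.7) / 0.7), 0.01)

  h <- hht_spectrum(imfset, fs, n_freq_bins = 100, n_time_bins = 40,
                    freq_range_hz = c(2, 500))
  # >= 90% of accumulated energy within +/- 5 Hz of 100 Hz (edges excluded)
  inner <- 3:38
  near <- abs(h$freq_axis - 100) <= 5
  expect_gt(sum(h$power[near, inner]) / sum(h$power[, inner]), 0.9)

  # linear chirp 50 -> 200 Hz: binned ridge increases, endpoints within 2 bins
  f0 <- 50; f1 <- 200
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) / (2 * max(t)) * t^2))
  ch_set <- structure(list(imfs = matrix(chirp, ncol = 1), residue = numeric(n)),
                      class = "fessemg_imfset")
  hc <- hht_spectrum(ch_set, fs, n_freq_bins = 60, n_time_bins = 20,
                     freq_range_hz = c(10, 400))
  ridge <- apply(hc$power, 2, which.max)
  # the first/last time bins carry Hilbert edge ripple; judge the interior
  interior <- 1:19
  expect_true(all(diff(ridge[interior]) >= 0))
  bin_hz <- diff(hc$freq_axis[1:2])
  expect_lt(abs(hc$freq_axis[ridge[2]] - f0), 2 * bin_hz)
  expect_lt(abs(hc$freq_axis[ridge[19]] - f1), 2 * bin_hz)

  # zero-content IMF set -> zero matrix; empty set -> error
  zset <- structure(list(imfs = matrix(0, n, 1), residue = numeric(n)),
                    class = "fessemg_imfset")
  expect_true(all(hht_spectrum(zset, fs)$power == 0))
  eset <- structure(list(imfs = matrix(numeric(0), n, 0), residue = numeric(n)),
                    class = "fessemg_imfset")
  expect_error(hht_spectrum(eset, fs), "empty")
})

test_that("rendering is shape-stable, scale-invariant and monotone", {
  m <- matrix(runif(300), 15, 20)
  img <- render_image(m, out_size = c(256, 256))
  expect_equal(dim(img$pixels), c(256, 256, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_true(all(is.finite(img$pixels)))

  # positive rescaling leaves the image unchanged (min-max normalization)
  img2 <- render_image(m * 37.5, out_size = c(256, 256))
  expect_equal(img$pixels, img2$pixels)

  # constant matrix -> constant image
  imgc <- render_image(matrix(3.3, 8, 8), out_size = c(64, 64))
  expect_equal(length(unique(as.vector(imgc$pixels[, , 1]))), 1)

  # monotone: colormap position follows matrix value ordering (linear)
  mm <- matrix(seq(0, 1, length.out = 64), 8, 8)
  iml <- render_image(mm, out_size = c(8, 8), scaling = "linear")
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  idx <- apply(matrix(aperm(iml$pixels, c(3, 1, 2)), nrow = 3), 2,
               function(px) which.min(colSums((pal - px)^2)))
  expect_true(all(diff(idx[order(mm)]) >= 0))

  expect_error(render_image(matrix(c(1, NaN, 3, 4), 2, 2)), "non-finite")
})

test_that("fatigue compression lowers the HHT energy-weighted mean frequency", {
  cfg <- fx_simconfig()
  ewmf <- function(fatigue, s) {
    rec <- generate_recording(cfg, "cycling", fatigue, 0.5, seed = s)
    w <- signal_window(rec$clean[1, ], 1L, 8000)
    d <- emd(w$samples)
    h <- hht_spectrum(d, 8000)
    sum(h$freq_axis * rowSums(h$power)) / sum(h$power)
  }
  d <- mean(sapply(1:10, function(s) ewmf("no_fatigue", s) - ewmf("extreme", s)))
  expect_gt(d, 0)
})
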