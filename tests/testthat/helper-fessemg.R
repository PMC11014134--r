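# Shared fixtures. Everything is generated in code and memoised within a
# test run so expensive signal synthesis happens once.

fx_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fx_env)) assign(key, expr, envir = fx_env)
  get(key, envir = fx_env)
}

fx_simconfig <- function(seed = 3, ...) simulation_config(seed = seed, ...)

# one contaminated window per (motion, fatigue, seed)
fx_window <- function(motion = "cycling", fatigue = "no_fatigue", seed = 11,
                      clean = FALSE) {
  key <- paste("win", motion, fatigue, seed, clean, sep = "_")
  memo(key, {
    cfg <- if (clean)
      simulation_config(stim_amplitude_ratio = 0, noise_rms = 0, seed = 3)
    else fx_simconfig()
    rec <- generate_recording(cfg, motion, fatigue, 0.5, seed = seed)
    w <- segment(rec, 0.5, 0)[[1]]
    attr(w, "clean_ref") <- rec$clean[1, ]
    w
  })
}

# pure-tone window helper
fx_tone <- function(freq_hz, n = 4000, fs = 8000, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  signal_window(amp * sin(2 * pi * freq_hz * t), channel_id = 1L,
                sampling_rate_hz = fs)
}

band_power_db <- function(x, fs, f0, half_width = 1) {
  p <- welch_psd(x, fs, nperseg = min(4000, length(x)))
  10 * log10(sum(p$psd[abs(p$freq - f0) <= half_width]))
}

# tiny trivially separable image dataset for network tests: class identity
# painted into disjoint image channels
fx_separable_examples <- function(reps = 3, size = 16) {
  out <- list()
  for (mi in seq_along(motion_labels()))
    for (fi in seq_along(fatigue_labels()))
      for (r in seq_len(reps)) {
        a <- array(0, c(size, size, 3))
        a[, , 1] <- (mi - 1) / 5
        a[, , 2] <- (fi - 1) / 2
        a[, , 3] <- 0.5
        out[[length(out) + 1]] <- labeled_example(
          lapply(1:4, function(b) a),
          motion_labels()[mi], fatigue_labels()[fi])
      }
  out
}

fx_tiny_model_config <- function(seed = 2, size = 16) {
  model_config(input_shape = c(size, size, 3), conv_channels = 4,
               motion_fc1 = 32, lstm_hidden = 16, fatigue_fc_dims = c(16, 3),
               dropout_rate = 0, seed = seed)
}
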