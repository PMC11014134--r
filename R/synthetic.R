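#' Simulation configuration for synthetic FES-contaminated sEMG
#'
#' Builds the configuration object for the synthetic generator that stands in
#' for the (private) experimental recordings: 4-channel sEMG at 8 kHz,
#' contaminated by a 20 Hz / 300 microsecond biphasic stimulation pulse
#' train. Channels are laid out as left tibialis anterior, left
#' gastrocnemius, right tibialis anterior, right gastrocnemius.
#'
#' The carrier is band-shaped Gaussian noise (support ~20-450 Hz, dominant
#' power 60-150 Hz). Muscle fatigue compresses the spectrum by
#' `fatigue_spectral_scale` (median frequency falls) and raises amplitude by
#' `fatigue_amplitude_gain`, the two canonical sEMG fatigue signatures. Each
#' motion has a distinct 4-channel activation-envelope pattern; ankle
#' dorsiflexion and plantarflexion are deliberately near-mirrors of each
#' other so that they are the hardest pair to separate, as in real lower-limb
#' data.
#'
#' @param sampling_rate_hz Sampling rate (default 8000).
#' @param n_channels Number of sEMG channels (default 4).
#' @param stim_freq_hz Stimulation pulse rate in Hz (default 20).
#' @param stim_pulse_width_s Per-phase pulse width in seconds (default 300e-6).
#' @param stim_amplitude_ratio Artifact peak as a multiple of the clean-signal
#'   RMS (default 10; set 0 to disable the artifact).
#' @param motion_envelopes Named list (one entry per motion) of per-channel
#'   envelope descriptors; see [default_motion_envelopes()].
#' @param fatigue_spectral_scale Named numeric, frequency-compression factor
#'   per fatigue level; must be strictly decreasing over
#'   (no_fatigue, medium, extreme) and lie in (0, 1].
#' @param fatigue_amplitude_gain Named numeric, RMS multiplier per fatigue
#'   level; non-decreasing, >= 1.
#' @param noise_rms Additive white measurement noise RMS (default 0.05,
#'   relative to the unit-RMS carrier).
#' @param seed Integer base seed; every recording derives its own stream.
#' @return Object of class `fessemg_simconfig`.
#' @export
simulation_config <- function(sampling_rate_hz = 8000,
                              n_channels = 4,
                              stim_freq_hz = 20,
                              stim_pulse_width_s = 300e-6,
                              stim_amplitude_ratio = 10,
                              motion_envelopes = default_motion_envelopes(),
                              fatigue_spectral_scale = c(no_fatigue = 1.0, medium = 0.85, extreme = 0.70),
                              fatigue_amplitude_gain = c(no_fatigue = 1.0, medium = 1.15, extreme = 1.30),
                              noise_rms = 0.05,
                              seed = 1L) {
  stopifnot(sampling_rate_hz > 0, n_channels >= 1, stim_freq_hz > 0,
            stim_pulse_width_s > 0, stim_amplitude_ratio >= 0, noise_rms >= 0)
  if (!all(MOTION_LABELS %in% names(motion_envelopes)))
    stop_input("motion_envelopes must have an entry for every motion label")
  for (lv in list(fatigue_spectral_scale, fatigue_amplitude_gain))
    if (!all(FATIGUE_LABELS %in% names(lv)))
      stop_input("fatigue maps must have an entry for every fatigue label")
  fss <- fatigue_spectral_scale[FATIGUE_LABELS]
  if (!(all(diff(fss) < 0) && all(fss > 0) && all(fss <= 1)))
    stop_input("fatigue_spectral_scale must be strictly decreasing over ",
               "(no_fatigue, medium, extreme) and lie in (0, 1]")
  fag <- fatigue_amplitude_gain[FATIGUE_LABELS]
  if (!(all(diff(fag) >= 0) && all(fag >= 1)))
    stop_input("fatigue_amplitude_gain must be non-decreasing and >= 1")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 n_channels = as.integer(n_channels),
                 stim_freq_hz = stim_freq_hz,
                 stim_pulse_width_s = stim_pulse_width_s,
                 stim_amplitude_ratio = stim_amplitude_ratio,
                 motion_envelopes = motion_envelopes,
                 fatigue_spectral_scale = fss,
                 fatigue_amplitude_gain = fag,
                 noise_rms = noise_rms,
                 seed = as.integer(seed)),
            class = "fessemg_simconfig")
}

#' Default per-motion activation-envelope patterns
#'
#' Each motion maps to four channel descriptors (tonic level, burst gain,
#' burst rate in Hz, burst duty cycle, phase as fraction of a cycle).
#' Patterns encode the physiology coarsely: tonic-low postural activity for
#' sitting; antiphase tibialis/gastrocnemius bursting with left-right
#' alternation for walking and stair climbing (different cadence and
#' co-contraction); single-muscle-dominant slow cycles for ankle
#' dorsiflexion (tibialis anterior) and plantarflexion (gastrocnemius) with
#' mutual cross-talk, making them the most confusable pair; and quadrature
#' four-channel bursting for cycling.
#'
#' @return Named list of 4-row descriptor data frames.
#' @export
default_motion_envelopes <- function() {
  ch <- function(tonic, gain, rate, duty, phase)
    data.frame(tonic = tonic, gain = gain, rate = rate, duty = duty, phase = phase)
  list(
    sitting = ch(tonic = rep(0.12, 4), gain = rep(0, 4), rate = rep(1, 4),
                 duty = rep(0.5, 4), phase = rep(0, 4)),
    walking = ch(tonic = rep(0.10, 4), gain = c(0.9, 0.8, 0.9, 0.8),
                 rate = rep(3.2, 4), duty = rep(0.35, 4),
                 phase = c(0, 0.5, 0.5, 0)),
    climbing_stairs = ch(tonic = rep(0.25, 4), gain = c(0.6, 1.0, 0.6, 1.0),
                         rate = rep(2.0, 4), duty = rep(0.5, 4),
                         phase = c(0, 0.5, 0.5, 0)),
    ankle_dorsiflexion = ch(tonic = c(0.15, 0.12, 0.15, 0.12),
                            gain = c(1.0, 0.35, 1.0, 0.35),
                            rate = rep(1.2, 4), duty = rep(0.5, 4),
                            phase = rep(0, 4)),
    ankle_plantarflexion = ch(tonic = c(0.12, 0.15, 0.12, 0.15),
                              gain = c(0.35, 1.0, 0.35, 1.0),
                              rate = rep(1.2, 4), duty = rep(0.5, 4),
                              phase = rep(0, 4)),
    cycling = ch(tonic = rep(0.15, 4), gain = rep(0.9, 4),
                 rate = rep(2.6, 4), duty = rep(0.5, 4),
                 phase = c(0, 0.25, 0.5, 0.75))
  )
}

#' Generate one synthetic FES-contaminated sEMG recording
#'
#' Builds a multi-channel recording as: fatigue-compressed band-shaped
#' Gaussian carrier, multiplied per channel by the motion's activation
#' envelope, scaled by the fatigue amplitude gain, plus a biphasic
#' rectangular stimulation pulse train (with an exponentially damped 80 Hz
#' M-wave surrogate after each pulse) at `stim_amplitude_ratio` times the
#' clean-signal RMS, plus white measurement noise. Deterministic given
#' `(seed, motion, fatigue, duration_s)`.
#'
#' @param config A [simulation_config()].
#' @param motion One of [motion_labels()].
#' @param fatigue One of [fatigue_labels()].
#' @param duration_s Duration in seconds, >= 0.5 (one analysis window).
#' @param seed Integer; defaults to a stream derived from `config$seed`,
#'   the motion and the fatigue level.
#' @return Object of class `fessemg_recording`: list with `samples`
#'   (channels x time matrix), `clean` (artifact- and noise-free ground
#'   truth, available because the data are synthetic), `sampling_rate_hz`,
#'   `motion_label`, `fatigue_label`, `stim_params`, `seed`.
#' @export
generate_recording <- function(config, motion, fatigue, duration_s,
                               seed = NULL) {
  stopifnot(inherits(config, "fessemg_simconfig"))
  check_motion(motion)
  check_fatigue(fatigue)
  if (!is.numeric(duration_s) || duration_s < 0.5)
    stop_input("duration_s must be >= 0.5 s (one analysis window)")
  if (is.null(seed))
    seed <- derive_seed(config$seed, match(motion, MOTION_LABELS),
                        match(fatigue, FATIGUE_LABELS))
  fs <- config$sampling_rate_hz
  n <- round(duration_s * fs)
  nc <- config$n_channels
  env_desc <- config$motion_envelopes[[motion]]
  gamma0 <- config$fatigue_spectral_scale[[fatigue]]
  gain0 <- config$fatigue_amplitude_gain[[fatigue]]

  with_seed(seed, {
    # per-recording variability: global amplitude, spectral jitter, envelope phase
    amp_jit <- exp(stats::rnorm(1, 0, 0.10))
    gamma <- gamma0 * exp(stats::rnorm(1, 0, 0.03))
    gamma <- min(gamma, 1)
    phase_jit <- stats::runif(1)
    t <- (seq_len(n) - 1) / fs
    clean <- matrix(0, nrow = nc, ncol = n)
    for (c_i in seq_len(nc)) {
      d <- env_desc[min(c_i, nrow(env_desc)), ]
      act_level <- d$tonic + d$gain * d$duty * 0.5 # mean activation
      center_scale <- 0.7 + 0.8 * min(act_level, 0.6)
      carrier <- shaped_carrier(n, fs, gamma, center_scale)
      env <- activation_envelope(t, d$tonic, d$gain, d$rate, d$duty,
                                 d$phase + phase_jit)
      ch_jit <- exp(stats::rnorm(1, 0, 0.05))
      clean[c_i, ] <- carrier * env * gain0 * amp_jit * ch_jit
    }
    base_rms <- sqrt(mean(clean^2))
    x <- clean
    if (config$stim_amplitude_ratio > 0 && base_rms > 0) {
      art <- stim_artifact_train(n, fs, config$stim_freq_hz,
                                 config$stim_pulse_width_s,
                                 config$stim_amplitude_ratio * base_rms,
                                 phase = stats::runif(1))
      x <- x + matrix(art, nrow = nc, ncol = n, byrow = TRUE)
    }
    if (config$noise_rms > 0)
      x <- x + matrix(stats::rnorm(nc * n, 0, config$noise_rms), nrow = nc)
    structure(list(samples = x,
                   clean = clean,
                   sampling_rate_hz = fs,
                   motion_label = motion,
                   fatigue_label = fatigue,
                   stim_params = list(freq_hz = config$stim_freq_hz,
                                      pulse_width_s = config$stim_pulse_width_s,
                                      amplitude_ratio = config$stim_amplitude_ratio),
                   seed = as.integer(seed)),
              class = "fessemg_recording")
  })
}

#' @export
print.fessemg_recording <- function(x, ...) {
  cat("<fessemg_recording> ", nrow(x$samples), " ch x ", ncol(x$samples),
      " samples @ ", x$sampling_rate_hz, " Hz | motion=", x$motion_label,
      " fatigue=", x$fatigue_label, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Unit-RMS carrier: broadband 20-450 Hz floor plus a dominant 60-150 Hz
# band, both compressed by the fatigue factor gamma. The dominant band's
# center scales mildly with the channel's mean activation level
# (center_scale), mimicking the spectral rise that accompanies stronger
# contractions (recruitment of faster motor units); this gives each motion
# a per-channel spectral signature that survives per-image normalization.
shaped_carrier <- function(n, fs, gamma, center_scale = 1) {
  broad <- fft_bandpass(stats::rnorm(n), 20 * gamma, 450 * gamma, fs, order = 4)
  core <- fft_bandpass(stats::rnorm(n), 60 * gamma * center_scale,
                       150 * gamma * center_scale, fs, order = 4)
  x <- 0.45 * broad / stats::sd(broad) + 0.55 * core / stats::sd(core)
  x / sqrt(mean(x^2))
}

# Raised-cosine burst train envelope, clipped at a small positive floor.
activation_envelope <- function(t, tonic, gain, rate, duty, phase) {
  u <- (t * rate + phase) %% 1
  burst <- ifelse(u < duty, 0.5 * (1 - cos(2 * pi * u / duty)), 0)
  pmax(tonic + gain * burst, 0.02)
}

# Stimulation artifact: biphasic rectangular pulse, an exponential
# charge-recovery tail (electrode/amplifier recovery, ~6 ms time constant)
# and a damped 80 Hz oscillation (M-wave surrogate) after each pulse. The
# tail and ring give the train the strong low-harmonic line structure
# (20, 40, 60 ... Hz) seen in FES-contaminated sEMG; microsecond pulses
# alone would put almost all their energy in the kHz range.
stim_artifact_train <- function(n, fs, freq_hz, width_s, peak, phase = 0) {
  period <- fs / freq_hz
  wid <- max(1L, as.integer(round(width_s * fs)))
  art <- numeric(n)
  starts <- seq(1 + round(phase * period), n, by = period)
  tail_len <- max(2L, min(as.integer(round(0.040 * fs)),
                          as.integer(period) - 2L * wid))
  k <- seq_len(tail_len)
  tau_rec <- 0.008 * fs                  # charge-recovery decay
  tau_ring <- 0.010 * fs                 # M-wave decay
  after <- -0.9 * peak * exp(-k / tau_rec) +
    peak * exp(-k / tau_ring) * cos(2 * pi * 80 * k / fs)
  for (s in starts) {
    s <- as.integer(round(s))
    i1 <- s:min(s + wid - 1L, n)
    art[i1] <- art[i1] + peak
    i2 <- (s + wid):min(s + 2L * wid - 1L, n)
    if (i2[1] <= n) art[i2] <- art[i2] - peak
    if (s + 2L * wid <= n) {
      i3 <- (s + 2L * wid):min(s + 2L * wid + tail_len - 1L, n)
      art[i3] <- art[i3] + after[seq_along(i3)]
    }
  }
  art
}

#' Generate a balanced labeled dataset of recordings
#'
#' Emits `n_windows_per_class` recordings per motion class. The three
#' rehabilitation motions (ankle dorsiflexion, ankle plantarflexion,
#' cycling) cycle through the three fatigue levels (uniform when
#' `n_windows_per_class` is a multiple of 3); the daily-task motions
#' (sitting, walking, climbing stairs) are emitted with
#' `fatigue_label = "no_fatigue"`, matching the experimental design where
#' fatigue was only induced and rated during the rehabilitation exercises.
#'
#' @param config A [simulation_config()].
#' @param n_windows_per_class Recordings per motion class (>= 1).
#' @param duration_s Duration of each recording (default 0.5 s, one window).
#' @return List of `fessemg_recording`, with a `manifest` attribute
#'   (data frame: recording_id, motion, fatigue, seed).
#' @export
generate_dataset <- function(config, n_windows_per_class, duration_s = 0.5) {
  stopifnot(inherits(config, "fessemg_simconfig"), n_windows_per_class >= 1)
  recs <- list()
  rows <- list()
  idx <- 0L
  for (m_i in seq_along(MOTION_LABELS)) {
    motion <- MOTION_LABELS[m_i]
    rehab <- motion %in% REHAB_MOTIONS
    for (r in seq_len(n_windows_per_class)) {
      fatigue <- if (rehab) FATIGUE_LABELS[(r - 1L) %% 3L + 1L] else "no_fatigue"
      seed_r <- derive_seed(config$seed, m_i, match(fatigue, FATIGUE_LABELS), r)
      idx <- idx + 1L
      recs[[idx]] <- generate_recording(config, motion, fatigue, duration_s,
                                        seed = seed_r)
      rows[[idx]] <- data.frame(recording_id = sprintf("rec_%05d", idx),
                                motion = motion, fatigue = fatigue,
                                seed = seed_r)
    }
  }
  attr(recs, "manifest") <- do.call(rbind, rows)
  recs
}
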