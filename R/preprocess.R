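#' Construct a single-channel analysis window
#'
#' @param samples Numeric vector of samples.
#' @param channel_id Integer channel index.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param start_time_s Window start time within its recording.
#' @param motion_label,fatigue_label Labels copied from the recording.
#' @return Object of class `fessemg_window`.
#' @export
signal_window <- function(samples, channel_id, sampling_rate_hz,
                          start_time_s = 0,
                          motion_label = NA_character_,
                          fatigue_label = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) >= 1, sampling_rate_hz > 0)
  structure(list(samples = as.numeric(samples),
                 channel_id = as.integer(channel_id),
                 sampling_rate_hz = sampling_rate_hz,
                 start_time_s = start_time_s,
                 motion_label = motion_label,
                 fatigue_label = fatigue_label),
            class = "fessemg_window")
}

#' @export
print.fessemg_window <- function(x, ...) {
  cat("<fessemg_window> ch", x$channel_id, ", ", length(x$samples),
      " samples @ ", x$sampling_rate_hz, " Hz, t0=", x$start_time_s,
      "s | ", x$motion_label, "/", x$fatigue_label, "\n", sep = "")
  invisible(x)
}

#' Segment a recording into overlapping windows
#'
#' Slides a `window_s`-long window with stride `window_s * (1 -
#' overlap_fraction)` along each channel; the trailing partial window is
#' discarded. At the defaults used throughout the package (0.5 s windows at
#' 8 kHz) every window has exactly 4000 samples. Labels are copied from the
#' recording.
#'
#' @param recording A `fessemg_recording`.
#' @param window_s Window length in seconds (default 0.5).
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0.5, the
#'   common sEMG convention).
#' @return List of `fessemg_window`, ordered channel-major then time.
#' @export
segment <- function(recording, window_s = 0.5, overlap_fraction = 0.5) {
  stopifnot(inherits(recording, "fessemg_recording"))
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1)
    stop_input("overlap_fraction must lie in [0, 1)")
  fs <- recording$sampling_rate_hz
  n <- ncol(recording$samples)
  wlen <- as.integer(round(window_s * fs))
  if (wlen > n)
    stop_input("window (", wlen, " samples) longer than recording (", n, ")")
  stride <- max(1L, as.integer(round(wlen * (1 - overlap_fraction))))
  starts <- seq(1L, n - wlen + 1L, by = stride)
  out <- vector("list", nrow(recording$samples) * length(starts))
  k <- 0L
  for (ch in seq_len(nrow(recording$samples))) {
    for (s in starts) {
      k <- k + 1L
      out[[k]] <- signal_window(recording$samples[ch, s:(s + wlen - 1L)],
                                channel_id = ch, sampling_rate_hz = fs,
                                start_time_s = (s - 1L) / fs,
                                motion_label = recording$motion_label,
                                fatigue_label = recording$fatigue_label)
    }
  }
  out
}

#' Remove FES stimulation artifacts from a window
#'
#' Combined EMD + notch-filter suppression of the pulse-synchronous
#' stimulation artifact: (1) the window is EMD-decomposed; (2) IMFs whose
#' Welch-PSD power fraction within +/-1 Hz of the stimulation harmonics
#' `k * stim_freq_hz`, `k = 1..n_harmonics`, exceeds
#' `imf_line_ratio_threshold` are discarded (these carry the pulse train and
#' its M-wave ringing); (3) the signal is reconstructed from the remaining
#' IMFs plus residue; (4) zero-phase IIR notches at each harmonic clean up
#' residual line components. Zero-phase filtering is used because the
#' Hilbert-Huang instantaneous phase is computed downstream.
#'
#' Window length, channel id and labels are preserved.
#'
#' @param window A `fessemg_window`.
#' @param stim_freq_hz Stimulation frequency (default 20 Hz). Must satisfy
#'   `stim_freq_hz * n_harmonics < fs / 2`.
#' @param n_harmonics Number of harmonics notch-filtered (default 3:
#'   notching harmonics beyond 60 Hz digs into the dominant 60-150 Hz sEMG
#'   band and costs more signal than the line energy it removes).
#' @param imf_line_ratio_threshold Line-power fraction above which an IMF is
#'   discarded (default 0.6: because EMD mode-mixes the broadband artifact
#'   remnant with genuine sEMG, only near-pure line-carrier modes can be
#'   dropped without losing signal).
#' @param imf_harmonics Number of harmonics used in the IMF line-power
#'   criterion (default: same as `n_harmonics`). Only IMFs dominated by the
#'   low stimulation harmonics (typically the slow mode that collects the
#'   pulse-train fundamental and recovery tail) are discarded; the spiky
#'   broadband artifact remnant shares its modes with genuine sEMG through
#'   mode mixing, so those modes are kept and the line content is handled by
#'   the notch stage instead.
#' @param notch_bw_hz Absolute 3-dB notch bandwidth in Hz applied at every
#'   harmonic (default 3). A constant bandwidth keeps the per-harmonic
#'   quality factor `f0 / bw` growing with frequency, so higher-harmonic
#'   notches do not widen and eat into the 60-150 Hz sEMG power band, and
#'   the filter transient (`~1/(pi * bw)` seconds, here ~0.1 s) settles
#'   within a 0.5 s window at every harmonic.
#' @param notch_q Constant quality factor; overrides `notch_bw_hz` when set
#'   (bandwidth then scales as `f0 / Q`).
#' @param notch_passes Cascaded zero-phase passes per harmonic (default 2;
#'   a second pass doubles the stop-band depth in dB, overcoming the
#'   transient-limited depth a single pass achieves on a 0.5 s window).
#' @param max_imfs,sift_tolerance Passed to [emd()].
#' @return A cleaned `fessemg_window`.
#' @export
remove_fes_artifacts <- function(window, stim_freq_hz = 20, n_harmonics = 3,
                                 imf_line_ratio_threshold = 0.6,
                                 imf_harmonics = NULL,
                                 notch_bw_hz = 3, notch_q = NULL,
                                 notch_passes = 2,
                                 max_imfs = 10,
                                 sift_tolerance = 0.2) {
  stopifnot(inherits(window, "fessemg_window"))
  fs <- window$sampling_rate_hz
  if (!(stim_freq_hz > 0) || stim_freq_hz * n_harmonics >= fs / 2)
    stop_input("stim_freq_hz * n_harmonics must be below Nyquist")
  x <- window$samples
  if (all(x == 0)) return(window)
  harmonics <- stim_freq_hz * seq_len(n_harmonics)
  if (is.null(imf_harmonics)) imf_harmonics <- n_harmonics
  comb <- stim_freq_hz * seq_len(imf_harmonics)
  dec <- emd(x, max_imfs = max_imfs, sift_tolerance = sift_tolerance)
  y <- dec$residue
  if (n_imfs(dec) > 0) {
    for (j in seq_len(n_imfs(dec))) {
      imf <- dec$imfs[, j]
      frac <- line_power_fraction(imf, fs, comb, half_width_hz = 1)
      if (!is.na(frac) && frac > imf_line_ratio_threshold) next # drop artifact IMF
      y <- y + imf
    }
  }
  for (pass in seq_len(notch_passes)) {
    for (f0 in harmonics) {
      q <- if (is.null(notch_q)) f0 / notch_bw_hz else notch_q
      flt <- design_notch(f0, fs, Q = q)
      y <- filtfilt(flt$b, flt$a, y, padlen = min(length(y) - 1L, 2000L))
    }
  }
  out <- window
  out$samples <- y
  out
}

# Fraction of a signal's Welch-PSD power lying within +/- half_width_hz of
# any of the given line frequencies.
line_power_fraction <- function(x, fs, lines, half_width_hz = 1) {
  p <- welch_psd(x, fs, nperseg = min(4096, length(x)), overlap = 0.5)
  tot <- sum(p$psd)
  if (tot <= 0) return(NA_real_)
  in_band <- rep(FALSE, length(p$freq))
  for (f0 in lines)
    in_band <- in_band | abs(p$freq - f0) <= half_width_hz
  sum(p$psd[in_band]) / tot
}
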