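#' Time-domain features of an sEMG window (MAV, WL, ZC, SSC)
#'
#' The four classic time-domain features used with an LDA motion baseline:
#' mean absolute value, waveform length, zero crossings and slope-sign
#' changes, the latter two gated by a noise threshold `epsilon`.
#'
#' The waveform-length form follows the printed definition
#' `WL = (1/N) * sum(x[i+1] - x[i])` by default, which telescopes to
#' `(x[N] - x[1]) / N`; this is almost certainly a typo for the conventional
#' `sum(|x[i+1] - x[i]|)`, so `wl_form = "conventional"` selects that form
#' (see the methods vignette). The threshold is usually set as
#' `epsilon = R * rest RMS`, see [epsilon_from_rest()].
#'
#' @param window A `fessemg_window` (or numeric vector).
#' @param epsilon Nonnegative noise threshold for ZC and SSC (default 0).
#' @param wl_form `"printed"` (telescoping mean of differences) or
#'   `"conventional"` (sum of absolute differences).
#' @return Named numeric `c(MAV, WL, ZC, SSC)` with the window's labels
#'   attached as attributes.
#' @export
tdf_features <- function(window, epsilon = 0, wl_form = c("printed", "conventional")) {
  wl_form <- match.arg(wl_form)
  x <- if (inherits(window, "fessemg_window")) window$samples else as.numeric(window)
  n <- length(x)
  if (n == 0) stop_input("tdf_features: empty window")
  if (epsilon < 0) stop_input("epsilon must be >= 0")
  mav <- mean(abs(x))
  d <- diff(x)
  wl <- if (wl_form == "printed") sum(d) / n else sum(abs(d))
  zc <- if (n >= 2) sum(x[-n] * x[-1] < 0 & abs(x[-n] - x[-1]) > epsilon) else 0
  ssc <- if (n >= 3) {
    xm <- x[2:(n - 1)]
    sum((xm - x[1:(n - 2)]) * (xm - x[3:n]) > epsilon)
  } else 0
  out <- c(MAV = mav, WL = wl, ZC = zc, SSC = ssc)
  copy_label_attrs(out, window)
}

#' Time-frequency (fatigue) features of an sEMG window (RMS, iEMG, MF, MPF)
#'
#' Amplitude features (root-mean-square and integrated EMG) plus the two
#' spectral fatigue indicators (median frequency and mean power frequency,
#' from a Welch PSD), used with an LDA fatigue baseline.
#'
#' @param window A `fessemg_window` (or numeric vector; then `fs` must be
#'   given).
#' @param psd_config List with Welch parameters `nperseg` (default 1024) and
#'   `overlap` (default 0.5).
#' @param fs Sampling rate, only needed for plain numeric input.
#' @return Named numeric `c(RMS, iEMG, MF, MPF)`; for an all-zero window the
#'   spectral features are 0, and for a window too short for a PSD estimate
#'   (< 8 samples) they are `NA`, in both cases with attribute
#'   `degenerate = TRUE`.
#' @export
tff_features <- function(window, psd_config = list(nperseg = 1024, overlap = 0.5),
                         fs = NULL) {
  if (inherits(window, "fessemg_window")) {
    x <- window$samples
    fs <- window$sampling_rate_hz
  } else {
    x <- as.numeric(window)
    if (is.null(fs)) stop_input("fs required for plain numeric input")
  }
  if (length(x) == 0) stop_input("tff_features: empty window")
  rms <- sqrt(mean(x^2))
  iemg <- sum(abs(x))
  degenerate <- all(x == 0) || length(x) < 8
  if (all(x == 0)) {
    mf <- 0; mpf <- 0
  } else if (length(x) < 8) {
    # too short for a PSD estimate; amplitude features remain valid
    mf <- NA_real_; mpf <- NA_real_
  } else {
    p <- welch_psd(x, fs, nperseg = min(psd_config$nperseg %||% 1024, length(x)),
                   overlap = psd_config$overlap %||% 0.5)
    mf <- median_frequency(p$freq, p$psd)
    mpf <- mean_power_frequency(p$freq, p$psd)
  }
  out <- c(RMS = rms, iEMG = iemg, MF = mf, MPF = mpf)
  if (degenerate) attr(out, "degenerate") <- TRUE
  copy_label_attrs(out, window)
}

copy_label_attrs <- function(values, window) {
  if (inherits(window, "fessemg_window")) {
    attr(values, "motion_label") <- window$motion_label
    attr(values, "fatigue_label") <- window$fatigue_label
    attr(values, "channel_id") <- window$channel_id
  }
  values
}

#' Noise threshold from a rest-segment recording
#'
#' `epsilon = R * RMS(rest segment)`, the usual rule for the ZC/SSC gates;
#' `R` is swept over 0..6 in steps of 0.02 and chosen by validation
#' accuracy, see [select_zc_epsilon()].
#'
#' @param rest_samples Samples of a designated rest-state signal (e.g.
#'   sitting / no-fatigue windows).
#' @param R Multiplier.
#' @return Nonnegative threshold.
#' @export
epsilon_from_rest <- function(rest_samples, R) {
  stopifnot(R >= 0)
  R * sqrt(mean(as.numeric(rest_samples)^2))
}

#' Select the ZC/SSC threshold multiplier by validation accuracy
#'
#' Sweeps `R` over `r_grid`, computing TDF features with
#' `epsilon = R * rest_rms` on the training and validation sets, fitting an
#' LDA on the training features, and returning the `R` (first in grid order
#' on ties) maximizing validation accuracy.
#'
#' @param train_examples,val_examples Lists of per-example window lists (one
#'   window per channel).
#' @param train_labels,val_labels Class labels.
#' @param rest_rms RMS of the designated rest signal.
#' @param r_grid Multiplier grid (default `seq(0, 6, by = 0.02)`).
#' @param wl_form Passed to [tdf_features()].
#' @return List with `R`, `epsilon` and `val_accuracy`.
#' @export
select_zc_epsilon <- function(train_examples, train_labels,
                              val_examples, val_labels, rest_rms,
                              r_grid = seq(0, 6, by = 0.02),
                              wl_form = "printed") {
  best <- list(R = r_grid[1], epsilon = 0, val_accuracy = -Inf)
  for (R in r_grid) {
    eps <- rest_rms * R
    ftr <- example_feature_matrix(train_examples, "tdf", epsilon = eps,
                                  wl_form = wl_form)
    fva <- example_feature_matrix(val_examples, "tdf", epsilon = eps,
                                  wl_form = wl_form)
    fit <- lda_fit(ftr, train_labels)
    acc <- mean(lda_predict(fit, fva) == val_labels)
    if (acc > best$val_accuracy)
      best <- list(R = R, epsilon = eps, val_accuracy = acc)
  }
  best
}

#' Per-example feature matrix (channels concatenated)
#'
#' Extracts TDF or TFF features for each channel window of each example and
#' concatenates them, giving one row per example (`4 channels x 4 features =
#' 16` columns at the defaults).
#'
#' @param examples List; each element is a list of per-channel
#'   `fessemg_window`s for one time window.
#' @param type `"tdf"` or `"tff"`.
#' @param epsilon Threshold for TDF features.
#' @param wl_form Passed to [tdf_features()].
#' @param psd_config Passed to [tff_features()].
#' @return Numeric matrix, one row per example, named columns
#'   (`ch<i>_<feature>`).
#' @export
example_feature_matrix <- function(examples, type = c("tdf", "tff"),
                                   epsilon = 0, wl_form = "printed",
                                   psd_config = list(nperseg = 1024, overlap = 0.5)) {
  type <- match.arg(type)
  rows <- lapply(examples, function(ex) {
    feats <- lapply(ex, function(w) {
      if (type == "tdf") tdf_features(w, epsilon = epsilon, wl_form = wl_form)
      else tff_features(w, psd_config = psd_config)
    })
    unlist(lapply(seq_along(feats), function(i) {
      v <- feats[[i]]
      names(v) <- paste0("ch", i, "_", names(v))
      v
    }))
  })
  do.call(rbind, rows)
}
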