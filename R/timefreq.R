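#' Short-time Fourier spectrogram of a window
#'
#' Hann-tapered, hop-advanced DFT frames; returns the one-sided power
#' `|X(t,f)|^2` (interior bins doubled so the one-sided sum equals the
#' two-sided sum exactly, which keeps the Parseval identity testable).
#' Defaults (256-sample taper, hop 32) put the native grid near 256x256 for
#' a 4000-sample window.
#'
#' @param window A `fessemg_window`.
#' @param fft_window_len Frame length in samples (default 256).
#' @param hop Hop size in samples (default 32).
#' @param taper Taper name; only `"hann"` is implemented.
#' @return Object of class `fessemg_tfmat`: list with `power`
#'   (freq x time matrix), `freq_axis` (Hz, ascending), `time_axis` (s,
#'   frame centers) and `method = "STFT"`.
#' @export
stft_spectrogram <- function(window, fft_window_len = 256, hop = 32,
                             taper = "hann") {
  stopifnot(inherits(window, "fessemg_window"))
  if (!identical(taper, "hann"))
    stop_input("unknown taper: ", taper, " (only 'hann' is implemented)")
  x <- window$samples
  n <- length(x)
  if (fft_window_len > n) stop_input("fft_window_len exceeds window length")
  if (hop < 1) stop_input("hop must be >= 1")
  fs <- window$sampling_rate_hz
  w <- hann_taper(fft_window_len)
  starts <- seq(1L, n - fft_window_len + 1L, by = hop)
  nf <- fft_window_len %/% 2 + 1
  frames <- vapply(starts, function(s) x[s:(s + fft_window_len - 1L)] * w,
                   numeric(fft_window_len))
  X <- stats::mvfft(frames)[seq_len(nf), , drop = FALSE]
  p <- Mod(X)^2
  inner <- 2:(nf - if (fft_window_len %% 2 == 0) 1 else 0)
  p[inner, ] <- 2 * p[inner, ]
  structure(list(power = p,
                 freq_axis = seq(0, fs / 2, length.out = nf),
                 time_axis = (starts - 1 + fft_window_len / 2) / fs,
                 method = "STFT"),
            class = "fessemg_tfmat")
}

#' Bump-wavelet scalogram of a window
#'
#' Continuous wavelet transform with the analytic bump mother wavelet
#' (frequency-domain support `(mu - sigma, mu + sigma)` in `s * omega`),
#' L2-normalized (`1/sqrt(s)`), over `n_scales` logarithmically spaced
#' scales whose center frequencies span `freq_range_hz`. Returns squared
#' magnitude, rows ordered by ascending center frequency.
#'
#' @param window A `fessemg_window`.
#' @param n_scales Number of scales (default 64).
#' @param freq_range_hz Center-frequency range `(low, high)` in Hz,
#'   `0 < low < high <= fs/2` (default `c(10, 500)`, the sEMG band).
#' @param mu,sigma Bump wavelet parameters (defaults 5 and 0.6, the common
#'   choices for the bump family).
#' @return Object of class `fessemg_tfmat` with `method = "CWT"`.
#' @export
cwt_scalogram <- function(window, n_scales = 64, freq_range_hz = c(10, 500),
                          mu = 5, sigma = 0.6) {
  stopifnot(inherits(window, "fessemg_window"))
  fs <- window$sampling_rate_hz
  low <- freq_range_hz[1]; high <- freq_range_hz[2]
  if (!(low > 0 && high > low && high <= fs / 2))
    stop_input("freq_range_hz must satisfy 0 < low < high <= fs/2")
  x <- window$samples
  n <- length(x)
  fc <- exp(seq(log(low), log(high), length.out = n_scales)) # ascending Hz
  scales <- mu * fs / (2 * pi * fc)                          # descending
  X <- stats::fft(x)
  omega <- 2 * pi * (seq_len(n) - 1) / n                     # rad/sample, >= 0
  power <- matrix(0, nrow = n_scales, ncol = n)
  for (i in seq_len(n_scales)) {
    s <- scales[i]
    u <- (s * omega - mu) / sigma
    psi <- numeric(n)
    sup <- which(abs(u) < 1)
    psi[sup] <- exp(1 - 1 / (1 - u[sup]^2))
    W <- stats::fft(X * sqrt(s) * psi, inverse = TRUE) / n
    power[i, ] <- Mod(W)^2
  }
  structure(list(power = power,
                 freq_axis = fc,
                 time_axis = (seq_len(n) - 1) / fs,
                 method = "CWT"),
            class = "fessemg_tfmat")
}

#' Hilbert-Huang spectrum of an IMF set
#'
#' For each IMF the analytic signal gives instantaneous amplitude `a(t)` and
#' phase; instantaneous frequency is the phase derivative
#' (unwrap-then-differentiate, central differences). Amplitude (or, by
#' default, squared amplitude, energy-like) is accumulated at
#' `(t, omega(t))` on a time x frequency bin grid; contributions from all
#' IMFs are summed. Samples whose frequency estimate falls outside
#' `freq_range_hz` (e.g. negative estimates at the edges) are dropped.
#'
#' @param imfset An object from [emd()] with at least one IMF.
#' @param sampling_rate_hz Sampling rate of the decomposed signal in Hz.
#' @param n_freq_bins,n_time_bins Grid size (defaults 128 x 128).
#' @param freq_range_hz Frequency range `(low, high)` in Hz covered by the
#'   bins (default `c(2, 500)`).
#' @param mode `"energy"` accumulates `a(t)^2` (default, image rendering is
#'   brightness-like); `"amplitude"` accumulates `a(t)`.
#' @return Object of class `fessemg_tfmat` with `method = "HHT"`; rows are
#'   frequency-bin centers ascending.
#' @export
hht_spectrum <- function(imfset, sampling_rate_hz, n_freq_bins = 128,
                         n_time_bins = 128, freq_range_hz = c(2, 500),
                         mode = c("energy", "amplitude")) {
  stopifnot(inherits(imfset, "fessemg_imfset"))
  mode <- match.arg(mode)
  if (n_imfs(imfset) < 1) stop_input("hht_spectrum: empty IMF set")
  fs <- sampling_rate_hz
  low <- freq_range_hz[1]; high <- freq_range_hz[2]
  stopifnot(low > 0, high > low, high <= fs / 2)
  n <- nrow(imfset$imfs)
  tbin <- pmin(pmax(ceiling(seq_len(n) / n * n_time_bins), 1L), n_time_bins)
  H <- matrix(0, nrow = n_freq_bins, ncol = n_time_bins)
  for (j in seq_len(n_imfs(imfset))) {
    z <- hilbert_analytic(imfset$imfs[, j])
    a <- Mod(z)
    theta <- unwrap_phase(Arg(z))
    freq <- central_diff(theta) * fs / (2 * pi)
    ok <- which(freq >= low & freq <= high)
    if (!length(ok)) next
    fbin <- pmin(pmax(ceiling((freq[ok] - low) / (high - low) * n_freq_bins), 1L),
                 n_freq_bins)
    val <- if (mode == "energy") a[ok]^2 else a[ok]
    for (k in seq_along(ok))
      H[fbin[k], tbin[ok[k]]] <- H[fbin[k], tbin[ok[k]]] + val[k]
  }
  df <- (high - low) / n_freq_bins
  structure(list(power = H,
                 freq_axis = low + (seq_len(n_freq_bins) - 0.5) * df,
                 time_axis = ((seq_len(n_time_bins) - 0.5) / n_time_bins) * n / fs,
                 method = "HHT"),
            class = "fessemg_tfmat")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

central_diff <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d
}

#' @export
print.fessemg_tfmat <- function(x, ...) {
  cat("<fessemg_tfmat> ", x$method, " ", nrow(x$power), " freq x ",
      ncol(x$power), " time\n", sep = "")
  invisible(x)
}

#' Render a time-frequency matrix as a 256 x 256 x 3 image
#'
#' Per-image min-max normalization, optional logarithmic contrast, bilinear
#' resize to `out_size`, and mapping through a perceptually uniform
#' 3-channel colormap. Deterministic, and invariant to positive rescaling of
#' the input matrix. A constant matrix maps to a constant image.
#'
#' @param tf A `fessemg_tfmat` (or plain numeric matrix).
#' @param out_size Output `(rows, cols)`; default `c(256, 256)`.
#' @param colormap An `grDevices::hcl.colors` palette name (default
#'   `"viridis"`).
#' @param scaling `"linear"` or `"log"` (log1p contrast on the normalized
#'   values).
#' @param channel_id,motion_label,fatigue_label Optional metadata copied to
#'   the image (taken from `tf` attributes when absent).
#' @param norm_range Optional `(min, max)` used for normalization instead of
#'   the image's own range — lets the channels of one multi-channel window
#'   share a scale so inter-channel amplitude ratios survive rendering.
#' @return Object of class `fessemg_tfimage`: list with `pixels`
#'   (`out_size[1] x out_size[2] x 3` array in `[0,1]`, rows = frequency
#'   ascending), `method`, `freq_axis`, `time_axis` and the window metadata.
#' @export
render_image <- function(tf, out_size = c(256, 256), colormap = "viridis",
                         scaling = c("linear", "log"),
                         channel_id = NA_integer_,
                         motion_label = NA_character_,
                         fatigue_label = NA_character_,
                         norm_range = NULL) {
  scaling <- match.arg(scaling)
  if (inherits(tf, "fessemg_tfmat")) {
    m <- tf$power; method <- tf$method
    fax <- tf$freq_axis; tax <- tf$time_axis
  } else {
    m <- tf; method <- NA_character_
    fax <- seq_len(nrow(m)); tax <- seq_len(ncol(m))
  }
  if (!is.matrix(m) || length(m) == 0) stop_input("render_image: empty matrix")
  if (any(!is.finite(m))) stop_input("render_image: non-finite values in input")
  rng <- if (is.null(norm_range)) range(m) else norm_range
  v <- if (rng[2] > rng[1])
    pmin(pmax((m - rng[1]) / (rng[2] - rng[1]), 0), 1)
  else m * 0
  if (scaling == "log") v <- log1p(99 * v) / log(100)
  v <- bilinear_resize(v, out_size[1], out_size[2])
  pal <- grDevices::hcl.colors(256, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- pmin(pmax(1L, as.integer(round(v * 255)) + 1L), 256L)
  px <- array(0, dim = c(out_size[1], out_size[2], 3))
  for (c_i in 1:3) px[, , c_i] <- matrix(rgb[c_i, idx], nrow = out_size[1])
  structure(list(pixels = px,
                 method = method,
                 freq_axis = resample_axis(fax, out_size[1]),
                 time_axis = resample_axis(tax, out_size[2]),
                 channel_id = channel_id,
                 motion_label = motion_label,
                 fatigue_label = fatigue_label),
            class = "fessemg_tfimage")
}

#' @export
print.fessemg_tfimage <- function(x, ...) {
  cat("<fessemg_tfimage> ", x$method, " ", paste(dim(x$pixels), collapse = "x"),
      " | ch", x$channel_id, " ", x$motion_label, "/", x$fatigue_label,
      "\n", sep = "")
  invisible(x)
}

# Bilinear resampling of a matrix to nr x nc. When downscaling by 2x or
# more, blocks are box-averaged first so that sparse matrices (e.g. a
# Hilbert scatter) are aggregated rather than point-sampled.
bilinear_resize <- function(m, nr, nc) {
  fr <- floor(nrow(m) / nr); fc <- floor(ncol(m) / nc)
  if (fr >= 2 || fc >= 2) m <- box_average(m, max(fr, 1L), max(fc, 1L))
  sr <- nrow(m); sc <- ncol(m)
  if (sr == nr && sc == nc) return(m)
  ri <- if (nr == 1) rep(1, 1) else seq(1, sr, length.out = nr)
  ci <- if (nc == 1) rep(1, 1) else seq(1, sc, length.out = nc)
  r0 <- pmin(floor(ri), sr - 1L); r0[sr == 1] <- 1
  c0 <- pmin(floor(ci), sc - 1L); c0[sc == 1] <- 1
  if (sr == 1) { r0 <- rep(1, nr); fr <- rep(0, nr) } else fr <- ri - r0
  if (sc == 1) { c0 <- rep(1, nc); fc <- rep(0, nc) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, sr); c1 <- pmin(c0 + 1L, sc)
  a <- m[r0, c0, drop = FALSE]; b <- m[r1, c0, drop = FALSE]
  cc <- m[r0, c1, drop = FALSE]; d <- m[r1, c1, drop = FALSE]
  wr <- matrix(fr, nrow = nr, ncol = nc)
  wc <- matrix(fc, nrow = nr, ncol = nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc + d * wr * wc
}

# Mean over fr x fc blocks (trailing partial blocks folded into the last).
box_average <- function(m, fr, fc) {
  if (fr > 1) {
    g <- pmin(ceiling(seq_len(nrow(m)) / fr), nrow(m) %/% fr)
    m <- apply(m, 2, function(col) tapply(col, g, mean))
  }
  if (fc > 1) {
    g <- pmin(ceiling(seq_len(ncol(m)) / fc), ncol(m) %/% fc)
    m <- t(apply(m, 1, function(row) tapply(row, g, mean)))
  }
  m
}

resample_axis <- function(ax, n_out) {
  if (length(ax) == n_out) return(ax)
  stats::approx(seq_along(ax), ax, n = n_out)$y
}

#' Convert a window into a rendered time-frequency image
#'
#' Convenience wrapper running one of the three transforms and
#' [render_image()], copying the window's metadata onto the image.
#'
#' @param window A `fessemg_window`.
#' @param method `"STFT"`, `"CWT"` or `"HHT"`.
#' @param out_size Image size (default `c(256, 256)`).
#' @param scaling Contrast scaling for [render_image()]; default `"log"`
#'   (energy-like quantities span decades).
#' @param norm_range Passed to [render_image()].
#' @param ... Extra arguments for the underlying transform.
#' @return A `fessemg_tfimage`.
#' @export
window_tf_image <- function(window, method = c("HHT", "STFT", "CWT"),
                            out_size = c(256, 256), scaling = "log",
                            norm_range = NULL, ...) {
  method <- match.arg(method)
  tf <- window_tf_matrix(window, method, ...)
  render_image(tf, out_size = out_size, scaling = scaling,
               norm_range = norm_range,
               channel_id = window$channel_id,
               motion_label = window$motion_label,
               fatigue_label = window$fatigue_label)
}

#' Time-frequency matrix of a window by method name
#'
#' @inheritParams window_tf_image
#' @return A `fessemg_tfmat`.
#' @export
window_tf_matrix <- function(window, method = c("HHT", "STFT", "CWT"), ...) {
  method <- match.arg(method)
  switch(method,
    STFT = stft_spectrogram(window, ...),
    CWT = cwt_scalogram(window, ...),
    HHT = {
      dec <- emd(window$samples)
      if (n_imfs(dec) == 0) {
        structure(list(power = matrix(0, 128, 128),
                       freq_axis = seq(2, 500, length.out = 128),
                       time_axis = seq_len(128), method = "HHT"),
                  class = "fessemg_tfmat")
      } else hht_spectrum(dec, window$sampling_rate_hz, ...)
    })
}

#' Render the channels of one window jointly
#'
#' Computes the chosen transform for each per-channel window and renders
#' all images with a shared normalization range (`per_example`, the
#' default) so that inter-channel amplitude ratios — the primary
#' physiological cue for which muscle drives a motion — survive rendering;
#' `per_image` reproduces independent normalization.
#'
#' @param windows List of per-channel `fessemg_window`s of one time window.
#' @param method,out_size,scaling As in [window_tf_image()].
#' @param normalization `"per_example"` or `"per_image"`.
#' @return List of `fessemg_tfimage`.
#' @export
example_tf_images <- function(windows, method = c("HHT", "STFT", "CWT"),
                              out_size = c(256, 256), scaling = "log",
                              normalization = c("per_example", "per_image")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  tfs <- lapply(windows, window_tf_matrix, method = method)
  rng <- if (normalization == "per_example")
    range(unlist(lapply(tfs, function(tf) range(tf$power))))
  else NULL
  Map(function(tf, w) {
    render_image(tf, out_size = out_size, scaling = scaling,
                 norm_range = rng,
                 channel_id = w$channel_id,
                 motion_label = w$motion_label,
                 fatigue_label = w$fatigue_label)
  }, tfs, windows)
}
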