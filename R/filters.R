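#' Band-shaped noise via a Butterworth-magnitude response
#'
#' Applies an order-`order` Butterworth band-pass magnitude response to `x`
#' in the frequency domain (zero phase by construction). Used by the
#' synthetic generator to shape white noise into an sEMG-like carrier.
#'
#' @param x Real signal.
#' @param low,high Band edges in Hz, `0 < low < high <= fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (response falls as `f^(-2*order)` outside
#'   the band).
#' @return Filtered signal, same length as `x`.
#' @export
fft_bandpass <- function(x, low, high, fs, order = 4) {
  n <- length(x)
  stopifnot(low > 0, high > low, high <= fs / 2, n > 1)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- ifelse(f > fs / 2, fs - f, f) # two-sided axis folded to magnitude
  f0 <- sqrt(low * high)
  bw <- high - low
  u <- ifelse(f == 0, Inf, (f^2 - f0^2) / (f * bw))
  H <- 1 / sqrt(1 + u^(2 * order))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Second-order IIR notch filter design
#'
#' RBJ-cookbook notch biquad at `f0` Hz with quality factor `Q`
#' (3-dB bandwidth `f0/Q`).
#'
#' @param f0 Notch frequency in Hz (0 < f0 < fs/2).
#' @param fs Sampling rate in Hz.
#' @param Q Quality factor.
#' @return List with numerator `b` and denominator `a` (both length 3,
#'   `a[1] == 1`).
#' @export
design_notch <- function(f0, fs, Q = 30) {
  stopifnot(f0 > 0, f0 < fs / 2, Q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Direct-form IIR filtering: FIR part via convolution filter (zero initial
# state), AR part via recursive filter (both C-level in stats::filter).
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(numeric(nb - 1), x)
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  y <- y[(nb - 1) + seq_along(x)]
  if (length(a) > 1) y <- stats::filter(y, -a[-1], method = "recursive")
  as.numeric(y)
}

#' Zero-phase IIR filtering
#'
#' Forward-backward application of an IIR filter with odd-reflection edge
#' padding, so the net phase response is zero and edge transients are
#' suppressed. Used for notch filtering ahead of phase-sensitive
#' (Hilbert-based) analysis.
#'
#' @param b,a Filter coefficients as from [design_notch()].
#' @param x Signal.
#' @param padlen Reflection pad length; default `3 * (max(length(a),
#'   length(b)) - 1) * 10`, capped at `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (n < 4) return(x)
  if (is.null(padlen)) padlen <- 3 * (max(length(a), length(b)) - 1) * 10
  padlen <- min(padlen, n - 1)
  # odd reflection about the end points
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xx <- c(pre, x, post)
  y <- iir_filter(b, a, xx)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Welch power spectral density estimate
#'
#' Mean of Hann-tapered overlapping periodograms, one-sided density scaling.
#'
#' @param x Real signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (clipped to `length(x)`).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 1024, overlap = 0.5) {
  n <- length(x)
  stopifnot(n >= 8, fs > 0, overlap >= 0, overlap < 1)
  nperseg <- min(nperseg, n)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_taper(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) * scale
    # double interior bins for one-sided density
    inner <- 2:(nf - if (nperseg %% 2 == 0) 1 else 0)
    p[inner] <- 2 * p[inner]
    acc <- acc + p
  }
  list(freq = seq(0, fs / 2, length.out = nf), psd = acc / length(starts))
}

#' Periodic Hann taper
#' @param n Length.
#' @return Numeric vector of taper weights.
#' @export
hann_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Median and mean power frequency of a PSD
#'
#' `median_frequency` returns the frequency splitting the integrated PSD into
#' equal halves (linear interpolation between bins); `mean_power_frequency`
#' the power-weighted mean frequency. Both decrease with muscle fatigue, the
#' classic spectral fatigue indicators.
#'
#' @param freq Frequencies in Hz.
#' @param psd Power spectral density values.
#' @return Frequency in Hz, or `NA` if total power is zero.
#' @export
median_frequency <- function(freq, psd) {
  tot <- sum(psd)
  if (tot <= 0) return(NA_real_)
  cs <- cumsum(psd) / tot
  i <- which(cs >= 0.5)[1]
  if (i == 1) return(freq[1])
  # linear interpolation inside bin i
  f0 <- freq[i - 1]; f1 <- freq[i]
  c0 <- cs[i - 1]; c1 <- cs[i]
  f0 + (0.5 - c0) / (c1 - c0) * (f1 - f0)
}

#' @rdname median_frequency
#' @export
mean_power_frequency <- function(freq, psd) {
  tot <- sum(psd)
  if (tot <= 0) return(NA_real_)
  sum(freq * psd) / tot
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: zeroes negative frequencies and doubles positive ones,
#' yielding `x + i * H[x]`.
#'
#' @param x Real signal.
#' @return Complex vector, the analytic signal of `x`.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
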