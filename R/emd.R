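#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by envelope
#' sifting: cubic-spline envelopes through local maxima and minima (with
#' mirrored end extension), iterated until the Cauchy standard-deviation
#' criterion falls below `sift_tolerance`, then repeated on the residue
#' until it is monotone (fewer than 3 extrema) or `max_imfs` is reached.
#' IMFs are returned highest-frequency first; by construction the residue is
#' `x - rowSums(imfs)`, so completeness is exact to floating-point error.
#'
#' @param x Finite numeric signal, length >= 8.
#' @param max_imfs Maximum number of IMFs (default 10, the usual cap for
#'   4000-sample sEMG windows).
#' @param sift_tolerance Cauchy/SD stopping tolerance for sifting
#'   (default 0.2, the canonical Huang value).
#' @param max_sift Per-IMF cap on sifting iterations.
#' @return An object of class `fessemg_imfset`: list with `imfs`
#'   (length-n columns, 0 or more) and `residue`.
#' @export
emd <- function(x, max_imfs = 10, sift_tolerance = 0.2, max_sift = 50) {
  if (!is.numeric(x) || length(x) < 8)
    stop_input("emd: input must be numeric with length >= 8")
  if (!all(is.finite(x)))
    stop_input("emd: input contains non-finite values")
  n <- length(x)
  residue <- as.numeric(x)
  imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  for (k in seq_len(max_imfs)) {
    ext <- find_extrema(residue)
    if (length(ext$max) + length(ext$min) < 3) break
    h <- residue
    for (it in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_crit < sift_tolerance) break
    }
    imfs <- cbind(imfs, h)
    residue <- residue - h
  }
  structure(list(imfs = imfs, residue = residue),
            class = "fessemg_imfset")
}

#' @export
print.fessemg_imfset <- function(x, ...) {
  cat("<fessemg_imfset> ", ncol(x$imfs), " IMF(s), length ",
      length(x$residue), "\n", sep = "")
  invisible(x)
}

#' Number of IMFs in an IMF set
#' @param imfset An object from [emd()].
#' @return Integer count.
#' @export
n_imfs <- function(imfset) ncol(imfset$imfs)

# Local extrema indices. Plateaus are collapsed to their midpoint.
find_extrema <- function(x) {
  d <- diff(x)
  # collapse exact plateaus by nudging via run-length midpoints on sign(d)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  s_f <- s
  # forward-fill zero signs so flat tops count once
  for (i in which(s_f == 0)) s_f[i] <- if (i > 1) s_f[i - 1] else 0
  chg <- which(s_f[-1] != s_f[-length(s_f)] & s_f[-length(s_f)] != 0) + 1L
  mx <- chg[s_f[chg - 1] > 0]
  mn <- chg[s_f[chg - 1] < 0]
  list(max = mx, min = mn)
}

# Mean of cubic-spline upper/lower envelopes, with mirror extension of the
# two nearest extrema beyond each end (standard boundary treatment).
# Returns NULL when either envelope cannot be formed.
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2) return(NULL)
  upper <- spline_envelope(ext$max, x, n)
  lower <- spline_envelope(ext$min, x, n)
  (upper + lower) / 2
}

spline_envelope <- function(idx, x, n) {
  xi <- idx
  yi <- x[idx]
  k <- min(2L, length(xi))
  # mirror the k nearest extrema about each end point
  pre_x <- 2 - xi[k:1]
  pre_y <- yi[k:1]
  m <- length(xi)
  post_x <- 2 * n - xi[m:(m - k + 1)]
  post_y <- yi[m:(m - k + 1)]
  xs <- c(pre_x, xi, post_x)
  ys <- c(pre_y, yi, post_y)
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}
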