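# Shared signal-processing helpers.

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) second-order Butterworth band-pass, the
#' filter used for offline slow-oscillation detection and threshold
#' computation.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric, low and high corner frequencies in Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return Filtered vector, same length as \code{x}.
#' @export
bandpassFilter <- function(x, fs, band, order = 2) {
  stopifnot(length(band) == 2L, band[1] < band[2], band[2] < fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Negative half-waves bounded by zero crossings.
#
# Returns a data.frame with one row per negative half-wave of x:
# start/end sample indices (first sample below zero, last sample below
# zero), the index and value of the minimum, and the index of the
# positive-going crossing (first sample >= 0 after the half-wave).
negativeHalfwaves <- function(x) {
  neg <- x < 0
  if (!any(neg)) {
    return(data.frame(start = integer(), end = integer(),
                      imin = integer(), vmin = numeric(),
                      iup = integer()))
  }
  d <- diff(c(FALSE, neg, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  # drop a half-wave truncated by the end of the signal (no confirming
  # positive-going crossing)
  keep <- ends < length(x)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(start = integer(), end = integer(),
                      imin = integer(), vmin = numeric(),
                      iup = integer()))
  }
  imin <- vapply(seq_along(starts), function(k) {
    seg <- starts[k]:ends[k]
    seg[which.min(x[seg])]
  }, integer(1))
  data.frame(start = starts, end = ends, imin = imin,
             vmin = x[imin], iup = ends + 1L)
}

# Analytic-signal envelope via FFT (Hilbert transform magnitude).
analyticEnvelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Sine tapers (Riedel-Sidorenko): k-th taper over n samples.
sineTapers <- function(n, k) {
  t(sapply(seq_len(k), function(j)
    sqrt(2 / (n + 1)) * sin(pi * j * seq_len(n) / (n + 1))))
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' 1/f background noise
#'
#' Generates Gaussian noise with a power spectrum proportional to
#' \eqn{1/f^\alpha} above a low-frequency knee (the spectrum is flat below
#' the knee so variance stays finite), scaled to a target standard
#' deviation. Uses FFT spectral shaping.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent alpha (default 1, pink noise).
#' @param sd target standard deviation, microvolt.
#' @param knee knee frequency in Hz below which the spectrum is flat.
#' @return Numeric vector of length \code{n}.
#' @export
oneOverFNoise <- function(n, fs, exponent = 1, sd = 1, knee = 0.5) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to two-sided frequency
  shape <- 1 / pmax(f, knee)^(exponent / 2)
  shape[1] <- 0                          # remove DC
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  x * sd / stats::sd(x)
}

# Uniform draw in [lo, hi].
runif1 <- function(lo, hi) stats::runif(1, lo, hi)
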