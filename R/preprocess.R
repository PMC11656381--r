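#' Interpolate a spectrum onto a uniform grid
#'
#' Linear interpolation onto `nPoints` equally spaced samples spanning
#' the original x range; the endpoints are preserved exactly. Linear
#' (rather than spline) interpolation avoids overshoot that would create
#' spurious curvature extrema in the second-derivative peak detector.
#'
#' @param s a [Spectrum-class].
#' @param nPoints number of output samples (>= 2).
#' @return The resampled [Spectrum-class].
#' @examples
#' interpolateUniform(Spectrum(c(0, 1), c(0, 1)), 3)
#' @export
interpolateUniform <- function(s, nPoints) {
  stopifnot(is(s, "Spectrum"))
  nPoints <- as.integer(nPoints)
  if (is.na(nPoints) || nPoints < 2L)
    stop("nPoints must be an integer >= 2")
  xi <- seq(s@x[1L], s@x[length(s@x)], length.out = nPoints)
  yi <- stats::approx(s@x, s@y, xout = xi, method = "linear",
                      rule = 2)$y
  initialize(s, x = xi, y = yi)
}

#' Moving-average denoising
#'
#' Centered boxcar smoothing: each sample is replaced by the mean of the
#' samples in a window of `window` points around it, truncated at the
#' array edges. Even windows take one extra sample on the left.
#' `repeats` applies the filter sequentially, so a cascade of shrinking
#' windows (e.g. 100, 30, 10) can be expressed either by repeated calls
#' or by `repeats` with a fixed window.
#'
#' @param s a [Spectrum-class].
#' @param window window size in samples, 1 <= window <= length(s);
#'   window = 1 is the identity.
#' @param repeats number of sequential applications (default 1).
#' @return The smoothed [Spectrum-class]; x is unchanged.
#' @examples
#' denoise(Spectrum(1:5, c(0, 0, 3, 0, 0)), window = 3)
#' @export
denoise <- function(s, window, repeats = 1L) {
  stopifnot(is(s, "Spectrum"))
  window <- as.integer(window)
  repeats <- as.integer(repeats)
  n <- length(s@y)
  if (is.na(window) || window < 1L || window > n)
    stop("window must be between 1 and length(s) = ", n)
  if (is.na(repeats) || repeats < 1L)
    stop("repeats must be >= 1")
  y <- s@y
  left <- as.integer(ceiling((window - 1L) / 2L))
  right <- as.integer(floor((window - 1L) / 2L))
  idx <- seq_len(n)
  lo <- pmax(idx - left, 1L)
  hi <- pmin(idx + right, n)
  for (r in seq_len(repeats)) {
    cs <- cumsum(c(0, y))
    y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  initialize(s, y = y)
}
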