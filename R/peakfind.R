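.checkUniform <- function(x, where) {
  h <- diff(x)
  if (max(h) - min(h) > 1e-8 * mean(h))
    stop(where, " requires a uniform grid; run interpolateUniform() first")
  mean(h)
}

#' Central second derivative on a uniform grid
#'
#' y''_i = (y_{i-1} - 2 y_i + y_{i+1}) / h^2 for interior points;
#' endpoints copy the nearest interior value. Exact for quadratics.
#'
#' @param s a [Spectrum-class] on a uniform grid (length >= 3).
#' @return Numeric vector of second derivatives, same length as s.
#' @export
secondDerivative <- function(s) {
  stopifnot(is(s, "Spectrum"))
  n <- length(s@y)
  if (n < 3L) stop("secondDerivative needs at least 3 points")
  h <- .checkUniform(s@x, "secondDerivative")
  y <- s@y
  d2 <- numeric(n)
  d2[2:(n - 1L)] <- (y[1:(n - 2L)] - 2 * y[2:(n - 1L)] + y[3:n]) / h^2
  d2[1L] <- d2[2L]
  d2[n] <- d2[n - 1L]
  d2
}

#' Candidate peak indices from curvature
#'
#' Indices where the negative second derivative is a strict local
#' maximum with positive curvature. Because overlapping components show
#' up as shoulders (curvature extrema) rather than maxima of y itself,
#' this curvature rule finds sub-peaks a plain local-maximum scan would
#' miss.
#'
#' @param s a [Spectrum-class] on a uniform grid.
#' @return Integer vector of 1-based candidate indices (possibly empty).
#' @export
candidateIndices <- function(s) {
  nd2 <- -secondDerivative(s)
  n <- length(nd2)
  h <- mean(diff(s@x))
  # curvature floor: second differences of smooth/affine signals carry
  # roundoff jitter of order eps*|y|/h^2, which must not spawn candidates
  floorCurv <- 1e-9 * max(abs(s@y), 1e-300) / h^2
  i <- 2:(n - 1L)
  cand <- i[nd2[i] > nd2[i - 1L] & nd2[i] > nd2[i + 1L] &
            nd2[i] > floorCurv]
  as.integer(cand)
}

#' Peak detection by window propagation
#'
#' A window of `windowSize` samples is propagated along the grid one
#' sample at a time (windows are truncated, not skipped, at the edges;
#' even sizes take the extra sample on the left). A curvature candidate
#' (see [candidateIndices()]) becomes a peak when it is the
#' best-supported candidate of the window centered on it: no other
#' candidate in that window has higher intensity (exact ties break
#' toward the smaller index), the in-window amplitude range
#' max(y) - min(y) reaches `threshold`, and the intensity at the
#' candidate reaches `minAmplitude`.
#'
#' Smaller windows admit more candidates (a sample is more likely to
#' dominate a short neighborhood than a long one), so the peak count is
#' non-increasing in `windowSize` wherever the threshold is passed at
#' the smallest window, and always non-increasing in `threshold` and
#' `minAmplitude`.
#'
#' @param s a [Spectrum-class] on a uniform grid, normally already
#'   detrended.
#' @param windowSize window length in samples (>= 3, <= length(s)).
#' @param threshold minimum in-window amplitude range (>= 0).
#' @param minAmplitude minimum intensity at the peak (>= 0).
#' @return A [PeakSet-class] sorted by x.
#' @export
detectPeaks <- function(s, windowSize = 10L, threshold = 0,
                        minAmplitude = 0) {
  stopifnot(is(s, "Spectrum"))
  windowSize <- as.integer(windowSize)
  n <- length(s@y)
  if (is.na(windowSize) || windowSize < 3L)
    stop("windowSize must be an integer >= 3")
  if (windowSize > n)
    stop("windowSize (", windowSize, ") exceeds spectrum length (", n, ")")
  if (threshold < 0 || minAmplitude < 0)
    stop("threshold and minAmplitude must be >= 0")
  y <- s@y
  cand <- candidateIndices(s)
  accepted <- integer(0)
  if (length(cand)) {
    left <- as.integer(ceiling((windowSize - 1L) / 2L))
    right <- as.integer(floor((windowSize - 1L) / 2L))
    # window bounds for every placement (centered at each sample,
    # truncated at the edges)
    ctr <- seq_len(n)
    lo <- pmax(ctr - left, 1L)
    hi <- pmin(ctr + right, n)
    # rolling min/max per placement via k-fold pmin/pmax over shifts
    winMin <- rep(Inf, n); winMax <- rep(-Inf, n)
    for (off in (-left):right) {
      j <- ctr + off
      ok <- j >= 1L & j <= n
      winMin[ok] <- pmin(winMin[ok], y[j[ok]])
      winMax[ok] <- pmax(winMax[ok], y[j[ok]])
    }
    isCand <- logical(n); isCand[cand] <- TRUE
    for (ci in cand) {
      if (y[ci] < minAmplitude) next
      if (winMax[ci] - winMin[ci] < threshold) next
      others <- cand[cand >= lo[ci] & cand <= hi[ci] & cand != ci]
      if (length(others)) {
        if (any(y[others] > y[ci])) next
        if (any(y[others] == y[ci] & others < ci)) next
      }
      accepted <- c(accepted, ci)
    }
  }
  d2 <- if (n >= 3L) secondDerivative(s) else numeric(n)
  pk <- data.frame(index = accepted, x = s@x[accepted],
                   amplitude = y[accepted],
                   curvature = -d2[accepted])
  new("PeakSet", peaks = pk, windowSize = windowSize,
      threshold = as.numeric(threshold),
      minAmplitude = as.numeric(minAmplitude))
}
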