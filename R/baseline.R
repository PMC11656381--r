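#' Second-order difference matrix
#'
#' The (n-2) x n operator D with rows (1, -2, 1); the penalty
#' lambda * ||D z||^2 enforces baseline smoothness in the penalized
#' least-squares solvers. Constant and affine vectors are in its null
#' space, so an unpenalized straight line is always attainable.
#'
#' @param n signal length (>= 3).
#' @param sparse return a sparse [Matrix::Matrix] (default) or dense.
#' @return The difference operator.
#' @examples
#' differenceMatrix(4, sparse = FALSE)
#' @export
differenceMatrix <- function(n, sparse = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("n must be >= 3 for a second-order difference matrix")
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L),
                                           rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  if (sparse) D else as.matrix(D)
}

#' Penalized least-squares smoother
#'
#' Solves (W + lambda D'D) z = W s for the baseline z minimizing
#' sum_i w_i (s_i - z_i)^2 + lambda ||D z||^2, with W = diag(w) and D
#' the second-order difference operator. The sparse banded system is
#' solved by a sparse Cholesky factorization.
#'
#' @param s numeric signal vector (length >= 3).
#' @param weights non-negative weight vector, same length as s.
#' @param lam smoothness penalty lambda > 0.
#' @return The baseline vector z.
#' @export
plsSolve <- function(s, weights, lam) {
  n <- length(s)
  if (n < 3L) stop("plsSolve needs length >= 3")
  if (length(weights) != n) stop("weights must match signal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0")
  D <- differenceMatrix(n)
  A <- Matrix::Diagonal(n, x = weights) + lam * Matrix::crossprod(D)
  z <- Matrix::solve(A, weights * s)
  as.numeric(z)
}

#' Straight-line baseline
#'
#' The line through the first and last point of the spectrum: fast,
#' shape-preserving, but blind to nonlinear drifts.
#'
#' @param s a [Spectrum-class].
#' @return A [BaselineResult-class] with method "linear".
#' @export
linearBaseline <- function(s) {
  stopifnot(is(s, "Spectrum"))
  x <- s@x; y <- s@y
  n <- length(x)
  slope <- (y[n] - y[1L]) / (x[n] - x[1L])
  z <- y[1L] + slope * (x - x[1L])
  new("BaselineResult", z = z, method = "linear", lam = NA_real_,
      ratio = NA_real_, nIter = 0L, converged = TRUE,
      weights = numeric(0))
}

#' Adaptive iteratively reweighted penalized least squares (airPLS)
#'
#' Iterates the penalized smoother with weights that are zero wherever
#' the signal sits above the current baseline (preserving peaks) and
#' grow exponentially with iteration number below it, so the baseline is
#' pulled into regions the signal undershoots. Iteration t uses
#' w_i = exp(t |d_i| / ||d-||_1) for d_i = s_i - z_i < 0 and w_i = 0 for
#' d_i >= 0, with the first and last weight anchored at
#' exp(t max(d-)/||d-||_1); it stops when ||d-||_1 < ratio * ||s||_1.
#'
#' @param s numeric intensity vector (length >= 3).
#' @param lam smoothness penalty (> 0); default 200.
#' @param ratio convergence ratio in (0, 1); default 1e-6.
#' @param maxIter maximum iterations (>= 1); default 50.
#' @return A [BaselineResult-class] with method "airpls".
#' @references Zhang, Z.-M., Chen, S., Liang, Y.-Z. (2010) Baseline
#'   correction using adaptive iteratively reweighted penalized least
#'   squares. Analyst 135, 1138-1146.
#' @export
airPLS <- function(s, lam = 200, ratio = 1e-6, maxIter = 50L) {
  n <- length(s)
  if (n < 3L) stop("airPLS needs length >= 3")
  if (lam <= 0) stop("lam must be > 0")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("maxIter must be >= 1")
  w <- rep(1, n)
  z <- s
  converged <- FALSE
  iters <- 0L
  absS <- sum(abs(s))
  for (t in seq_len(maxIter)) {
    z <- plsSolve(s, w, lam)
    if (!all(is.finite(z)))
      stop("airPLS produced a non-finite baseline at iteration ", t)
    iters <- t
    d <- s - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (!any(neg) || dssn < ratio * absS) { converged <- TRUE; break }
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    w[1L] <- exp(t * max(d[neg]) / dssn)
    w[n] <- w[1L]
  }
  new("BaselineResult", z = z, method = "airpls", lam = lam,
      ratio = ratio, nIter = iters, converged = converged, weights = w)
}

#' Asymmetrically reweighted penalized least squares (arPLS)
#'
#' Iterates the penalized smoother with logistic weights computed from
#' the statistics of the negative residuals d = s - z: with m and sigma
#' the mean and standard deviation of the negative part of d,
#' w_i = 1 / (1 + exp(2 (d_i - (2 sigma - m)) / sigma)). Samples far
#' above the baseline (peaks) get weight near 0, samples at or below it
#' weight near 1, so the estimated baseline stays underneath the peaks
#' and the detrended signal is primarily positive. Stops when the
#' relative change of the weight vector falls below `ratio`. If no
#' negative residuals remain (sigma undefined or 0) the current
#' baseline is returned as a degenerate success.
#'
#' @inheritParams airPLS
#' @return A [BaselineResult-class] with method "arpls"; per-iteration
#'   (mu, sigma) pairs are recorded in `diagnostics`.
#' @references Baek, S.-J., Park, A., Ahn, Y.-J., Choo, J. (2015)
#'   Baseline correction using asymmetrically reweighted penalized least
#'   squares smoothing. Analyst 140, 250-257.
#' @export
arPLS <- function(s, lam = 200, ratio = 1e-6, maxIter = 50L) {
  n <- length(s)
  if (n < 3L) stop("arPLS needs length >= 3")
  if (lam <= 0) stop("lam must be > 0")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("maxIter must be >= 1")
  w <- rep(1, n)
  z <- s
  converged <- FALSE
  iters <- 0L
  musig <- list()
  for (t in seq_len(maxIter)) {
    z <- plsSolve(s, w, lam)
    if (!all(is.finite(z)))
      stop("arPLS produced a non-finite baseline at iteration ", t)
    iters <- t
    d <- s - z
    dn <- d[d < 0]
    if (length(dn) < 2L) { converged <- TRUE; break }
    m <- mean(dn)
    sg <- stats::sd(dn)
    musig[[t]] <- c(mu = m, sigma = sg)
    if (sg == 0) { converged <- TRUE; break }
    wt <- 1 / (1 + exp(pmin(2 * (d - (2 * sg - m)) / sg, 700)))
    if (sqrt(sum((w - wt)^2)) / sqrt(sum(w^2)) < ratio) {
      converged <- TRUE
      w <- wt
      break
    }
    w <- wt
  }
  new("BaselineResult", z = z, method = "arpls", lam = lam,
      ratio = ratio, nIter = iters, converged = converged, weights = w,
      diagnostics = list(muSigma = musig))
}

#' Arpls-style logistic weights (exposed for inspection)
#'
#' @param d residual vector s - z.
#' @param m,sg mean and standard deviation of the negative part of d.
#' @return Weights in [0, 1], monotone non-increasing in d.
#' @keywords internal
arplsWeights <- function(d, m, sg) {
  1 / (1 + exp(pmin(2 * (d - (2 * sg - m)) / sg, 700)))
}

#' Detrend a spectrum by subtracting an estimated baseline
#'
#' Dispatches to [linearBaseline()], [airPLS()] or [arPLS()]; method
#' "none" returns the input unchanged with a zero baseline, so pipeline
#' stages can be disabled uniformly.
#'
#' @param s a [Spectrum-class].
#' @param method one of "linear", "airpls", "arpls", "none".
#' @param lam,ratio,maxIter passed to the PLS solvers.
#' @return A list with elements `spectrum` (the detrended
#'   [Spectrum-class]) and `baseline` (the [BaselineResult-class]).
#' @examples
#' s <- Spectrum(0:2, c(1, 9, 3))
#' detrend(s, "linear")$spectrum
#' @export
detrend <- function(s, method = c("arpls", "airpls", "linear", "none"),
                    lam = 200, ratio = 1e-6, maxIter = 50L) {
  stopifnot(is(s, "Spectrum"))
  method <- match.arg(method)
  res <- switch(method,
    none = new("BaselineResult", z = rep(0, length(s@y)),
               method = "none", lam = NA_real_, ratio = NA_real_,
               nIter = 0L, converged = TRUE, weights = numeric(0)),
    linear = linearBaseline(s),
    airpls = airPLS(s@y, lam = lam, ratio = ratio, maxIter = maxIter),
    arpls = arPLS(s@y, lam = lam, ratio = ratio, maxIter = maxIter))
  list(spectrum = initialize(s, y = s@y - res@z), baseline = res)
}
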