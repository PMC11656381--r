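# Independent reference implementations used as test oracles. All use
# dense base-R linear algebra and their own literal transcriptions of
# the update rules, so they share no code path with the package.

denseD2 <- function(n) {
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  D
}

densePlsSolve <- function(s, w, lam) {
  n <- length(s)
  D <- denseD2(n)
  A <- diag(w, n) + lam * crossprod(D)
  as.numeric(solve(A, w * s))
}

refAirPLS <- function(s, lam, ratio, maxIter) {
  n <- length(s)
  w <- rep(1, n)
  z <- s
  for (t in seq_len(maxIter)) {
    z <- densePlsSolve(s, w, lam)
    d <- s - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (!any(neg) || dssn < ratio * sum(abs(s))) break
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    w[1L] <- exp(t * max(d[neg]) / dssn)
    w[n] <- w[1L]
  }
  z
}

refArPLS <- function(s, lam, ratio, maxIter) {
  n <- length(s)
  w <- rep(1, n)
  z <- s
  for (t in seq_len(maxIter)) {
    z <- densePlsSolve(s, w, lam)
    d <- s - z
    dn <- d[d < 0]
    if (length(dn) < 2L) break
    m <- mean(dn); sg <- sd(dn)
    if (sg == 0) break
    wt <- 1 / (1 + exp(pmin(2 * (d - (2 * sg - m)) / sg, 700)))
    if (sqrt(sum((w - wt)^2)) / sqrt(sum(w^2)) < ratio) break
    w <- wt
  }
  z
}

bruteBoxcar <- function(y, window) {
  n <- length(y)
  left <- ceiling((window - 1) / 2)
  right <- floor((window - 1) / 2)
  vapply(seq_len(n), function(i)
    mean(y[max(1, i - left):min(n, i + right)]), numeric(1))
}

gaussD2 <- function(x, A, c0, s) {
  A * exp(-(x - c0)^2 / (2 * s^2)) * ((x - c0)^2 / s^4 - 1 / s^2)
}

# forward Bragg angle for a tetragonal reflection
forwardTwoTheta <- function(h, k, l, a, c, wavelength) {
  d <- 1 / sqrt((h^2 + k^2) / a^2 + l^2 / c^2)
  st <- wavelength / (2 * d)
  if (st >= 1) return(NA_real_)
  2 * asin(st) * 180 / pi
}
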