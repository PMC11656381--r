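#' Interplanar spacing from Bragg's law
#'
#' d = n lambda / (2 sin theta) with theta = twoTheta/2 (degrees at the
#' interface, radians internally). Strictly decreasing in twoTheta on
#' (0, 180).
#'
#' @param twoTheta diffraction angle 2-theta in degrees, in (0, 180].
#' @param wavelength incident wavelength in Angstrom (> 0); 1.54 A is
#'   typical for Cu K-alpha.
#' @param order diffraction order n (default 1).
#' @return Interplanar spacing d in Angstrom.
#' @examples
#' braggD(60, 1.0)    # 2 sin(30 deg) = 1, so d = 1
#' @export
braggD <- function(twoTheta, wavelength = 1.54, order = 1L) {
  if (any(twoTheta <= 0 | twoTheta > 180))
    stop("twoTheta must be in (0, 180] degrees")
  if (wavelength <= 0) stop("wavelength must be > 0")
  order * wavelength / (2 * sin(twoTheta / 2 * pi / 180))
}

#' Interplanar spacing of a tetragonal lattice
#'
#' 1/d^2 = (h^2 + k^2)/a^2 + l^2/c^2 for lattice constants a = b != c.
#' Symmetric under h <-> k and strictly decreasing in each index
#' magnitude.
#'
#' @param hkl integer triple (h, k, l), not all zero.
#' @param a,c lattice constants in Angstrom (> 0).
#' @return d_hkl in Angstrom.
#' @examples
#' tetragonalD(c(0, 0, 4), a = 3.785, c = 9.514)   # c/4
#' @export
tetragonalD <- function(hkl, a, c) {
  if (length(hkl) != 3L) stop("hkl must be a triple")
  if (all(hkl == 0)) stop("hkl must not be the zero triple")
  if (a <= 0 || c <= 0) stop("lattice constants must be > 0")
  1 / sqrt((hkl[1L]^2 + hkl[2L]^2) / a^2 + hkl[3L]^2 / c^2)
}

#' Assign Miller indices to observed reflections
#'
#' For each observed 2-theta, every triple with 0 <= h, k, l <= hklMax
#' (excluding (0,0,0)) is converted to a predicted 2-theta through the
#' tetragonal d-spacing and Bragg's law, and the triple minimizing the
#' absolute 2-theta residual is returned. Triples with h >= k represent
#' their h <-> k degenerate partners, and among exactly equal-d triples
#' the lexicographically smallest (h, k, l) wins, so ties resolve
#' deterministically and the canonical form (e.g. 1 0 1, not 0 1 1) is
#' reported. Triples whose d implies sin(theta) > 1 at the given
#' wavelength are geometrically unobservable and skipped.
#'
#' @param twoThetaList observed 2-theta values in degrees.
#' @param wavelength incident wavelength in Angstrom.
#' @param a,c tetragonal lattice constants in Angstrom.
#' @param hklMax largest index considered (default 6).
#' @param order diffraction order (default 1).
#' @return data.frame with columns two_theta, d, h, k, l, residual
#'   (degrees). An error is raised if some reflection admits no
#'   observable triple.
#' @examples
#' tt <- 2 * asin(1.54 / (2 * tetragonalD(c(1, 0, 3), 3.785, 9.514))) *
#'   180 / pi
#' assignMiller(tt, 1.54, a = 3.785, c = 9.514, hklMax = 4)
#' @export
assignMiller <- function(twoThetaList, wavelength = 1.54, a, c,
                         hklMax = 6L, order = 1L) {
  hklMax <- as.integer(hklMax)
  if (hklMax < 1L) stop("hklMax must be >= 1")
  if (any(twoThetaList <= 0 | twoThetaList >= 180))
    stop("observed twoTheta must be in (0, 180) degrees")
  grid <- expand.grid(h = 0:hklMax, k = 0:hklMax, l = 0:hklMax)
  grid <- grid[rowSums(grid) > 0, ]
  grid <- grid[grid$h >= grid$k, ]               # canonical h >= k
  # lexicographic order (h, k, l): earliest row wins on exact d ties
  grid <- grid[order(grid$h, grid$k, grid$l), ]
  d <- 1 / sqrt((grid$h^2 + grid$k^2) / a^2 + grid$l^2 / c^2)
  sinTheta <- order * wavelength / (2 * d)
  ok <- sinTheta < 1
  if (!any(ok))
    stop("no (h, k, l) triple is observable at wavelength ", wavelength)
  grid <- grid[ok, ]; d <- d[ok]
  ttPred <- 2 * asin(sinTheta[ok]) * 180 / pi
  out <- lapply(twoThetaList, function(tt) {
    res <- abs(ttPred - tt)
    i <- which.min(res)   # first minimum = lexicographically smallest
    data.frame(two_theta = tt, d = d[i], h = grid$h[i], k = grid$k[i],
               l = grid$l[i], residual = res[i])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
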