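.profileFamilies <- c("gaussian", "lorentzian", "voigt")
.lossNames <- c("linear", "soft_l1", "huber", "arctan")

#' Evaluate a single line profile
#'
#' All families are height-parameterized: the value at the center is
#' exactly `amplitude`.
#' \itemize{
#'   \item gaussian: A exp(-(x-c)^2 / (2 sigma^2))
#'   \item lorentzian: A gamma^2 / ((x-c)^2 + gamma^2) (half height at
#'     c +/- gamma)
#'   \item voigt: Gaussian-Lorentzian convolution evaluated through the
#'     Faddeeva function, Re w((x-c+i gamma)/(sigma sqrt 2)) scaled to A
#'     at the center; reduces to the Gaussian as gamma -> 0 and to the
#'     Lorentzian as sigma -> 0.
#' }
#' A true Voigt (not pseudo-Voigt) is used: the additive approximation
#' misstates wing weight at intermediate sigma/gamma.
#'
#' @param family "gaussian", "lorentzian" or "voigt".
#' @param center,amplitude,sigma,gamma profile parameters; widths for
#'   the active family must be > 0 (a Voigt with gamma = 0 is evaluated
#'   as the Gaussian limit and vice versa).
#' @param x evaluation grid.
#' @return Numeric vector of profile values.
#' @examples
#' profileEval("lorentzian", center = 0, amplitude = 2, gamma = 1,
#'             x = c(-1, 0, 1))
#' @export
profileEval <- function(family, center, amplitude, sigma = 0, gamma = 0,
                        x) {
  family <- match.arg(family, .profileFamilies)
  switch(family,
    gaussian = {
      if (sigma <= 0) stop("gaussian requires sigma > 0")
      amplitude * exp(-(x - center)^2 / (2 * sigma^2))
    },
    lorentzian = {
      if (gamma <= 0) stop("lorentzian requires gamma > 0")
      amplitude * gamma^2 / ((x - center)^2 + gamma^2)
    },
    voigt = {
      if (sigma <= 0 && gamma <= 0)
        stop("voigt requires sigma > 0 or gamma > 0")
      if (sigma <= 0)
        return(amplitude * gamma^2 / ((x - center)^2 + gamma^2))
      if (gamma <= 0)
        return(amplitude * exp(-(x - center)^2 / (2 * sigma^2)))
      z <- complex(real = (x - center) / (sigma * sqrt(2)),
                   imaginary = gamma / (sigma * sqrt(2)))
      z0 <- complex(real = 0, imaginary = gamma / (sigma * sqrt(2)))
      amplitude * Re(faddeeva(z)) / Re(faddeeva(z0))
    })
}

#' Sum of line profiles
#'
#' @param components data.frame with columns family, center, amplitude,
#'   sigma, gamma (one row per profile), as stored in a
#'   [Decomposition-class] or [GroundTruth-class].
#' @param x evaluation grid.
#' @return Elementwise sum of [profileEval()] over the rows.
#' @export
modelSum <- function(components, x) {
  stopifnot(nrow(components) >= 1L)
  y <- numeric(length(x))
  for (i in seq_len(nrow(components)))
    y <- y + profileEval(components$family[i], components$center[i],
                         components$amplitude[i], components$sigma[i],
                         components$gamma[i], x)
  y
}

# rho(u) on u = r^2 and its derivative, scale C fixed at 1 in units of
# the (typically max-normalized) signal
.rho <- function(u, loss) {
  switch(loss,
    linear = u,
    soft_l1 = 2 * (sqrt(1 + u) - 1),
    huber = ifelse(u <= 1, u, 2 * sqrt(u) - 1),
    arctan = atan(u))
}

.rhoPrime <- function(u, loss) {
  switch(loss,
    linear = rep(1, length(u)),
    soft_l1 = 1 / sqrt(1 + u),
    huber = ifelse(u <= 1, 1, 1 / sqrt(u)),
    arctan = 1 / (1 + u^2))
}

#' Robust decomposition objective
#'
#' S = sum_i rho(r_i^2) with r = modelSum(components, x) - sHat and rho
#' the chosen robust loss (scale 1): linear rho(u) = u gives the plain
#' sum of squares; soft_l1 rho(u) = 2(sqrt(1+u)-1); huber rho(u) = u for
#' u <= 1 else 2 sqrt(u) - 1; arctan rho(u) = atan(u). The sub-linear
#' losses damp the influence of outlying residuals.
#'
#' @param components profile table (see [modelSum()]).
#' @param sHat numeric detrended intensity vector.
#' @param x grid the intensities live on.
#' @param loss "linear", "soft_l1", "huber" or "arctan".
#' @return The scalar objective S >= 0.
#' @export
decompositionCost <- function(components, sHat, x, loss = "linear") {
  loss <- match.arg(loss, .lossNames)
  r <- modelSum(components, x) - sHat
  sum(.rho(r^2, loss))
}
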