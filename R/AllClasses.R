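#' @import methods
NULL

#' Spectrum: a one-dimensional spectroscopic signal
#'
#' Paired x/intensity vectors with axis metadata. `x` is in the
#' technique's units (wavenumber cm^-1 for Raman/IR, wavelength nm for
#' UV-vis, degrees two-theta for powder XRD); `y` is intensity in
#' arbitrary units. Every processing stage in the package consumes and
#' produces this class.
#'
#' Validity requires equal-length finite vectors of length >= 2 with
#' strictly increasing x.
#'
#' @slot x numeric, strictly increasing abscissa.
#' @slot y numeric, intensity.
#' @slot xLabel,yLabel character axis labels.
#'
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(x = "numeric", y = "numeric",
                 xLabel = "character", yLabel = "character"),
  prototype(xLabel = "x", yLabel = "intensity"),
  validity = function(object) {
    msg <- character()
    if (length(object@x) != length(object@y))
      msg <- c(msg, "x and y must have equal length")
    if (length(object@x) < 2L)
      msg <- c(msg, "a Spectrum needs at least 2 points")
    if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
      msg <- c(msg, "x and y must be finite")
    if (length(object@x) >= 2L && any(diff(object@x) <= 0))
      msg <- c(msg, "x must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct a Spectrum
#'
#' Points are sorted by x; exact duplicate x values are an error (they
#' would make downstream derivative operators ill-defined).
#'
#' @param x,y numeric vectors of equal length (>= 2), finite.
#' @param xLabel,yLabel axis labels.
#' @return A [Spectrum-class] object sorted by increasing x.
#' @examples
#' sp <- Spectrum(c(3, 1, 2), c(15, 10, 20))
#' xValues(sp)
#' @export
Spectrum <- function(x, y, xLabel = "x", yLabel = "intensity") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  o <- order(x)
  x <- x[o]; y <- y[o]
  d <- which(diff(x) == 0)
  if (length(d))
    stop("duplicate x value ", format(x[d[1L]]),
         ": duplicates are rejected because derivative-based stages ",
         "require a strictly increasing grid")
  new("Spectrum", x = x, y = y, xLabel = xLabel, yLabel = yLabel)
}

#' BaselineResult: an estimated baseline with solver diagnostics
#'
#' @slot z numeric estimated baseline, same length as the signal.
#' @slot method one of "linear", "airpls", "arpls", "none".
#' @slot lam smoothness penalty lambda (PLS methods; NA for linear).
#' @slot ratio convergence ratio used (PLS methods; NA for linear).
#' @slot nIter iterations performed.
#' @slot converged logical convergence flag.
#' @slot weights final diagonal of the weight matrix W (empty for linear).
#' @slot diagnostics list of per-iteration internals (e.g. mu/sigma of the
#'   negative residuals for arPLS).
#'
#' @aliases BaselineResult-class
#' @exportClass BaselineResult
setClass("BaselineResult",
  representation(z = "numeric", method = "character", lam = "numeric",
                 ratio = "numeric", nIter = "integer", converged = "logical",
                 weights = "numeric", diagnostics = "list"),
  prototype(diagnostics = list()),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@z)))
      msg <- c(msg, "baseline z must be finite")
    if (!object@method %in% c("linear", "airpls", "arpls", "none"))
      msg <- c(msg, "unknown baseline method")
    if (length(object@weights) && any(object@weights < 0))
      msg <- c(msg, "weights must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' PeakSet: peaks detected by window propagation
#'
#' `peaks` is a data.frame with one row per accepted peak and columns
#' `index` (1-based grid index), `x` (position), `amplitude` (intensity at
#' the peak) and `curvature` (negative second derivative at the peak;
#' positive for genuine maxima). Rows are sorted by x and indices are
#' unique.
#'
#' @slot peaks data.frame of accepted peaks.
#' @slot windowSize,threshold,minAmplitude detection parameters used.
#'
#' @aliases PeakSet-class
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "data.frame", windowSize = "integer",
                 threshold = "numeric", minAmplitude = "numeric"),
  validity = function(object) {
    p <- object@peaks
    need <- c("index", "x", "amplitude", "curvature")
    if (!all(need %in% names(p)))
      return("peaks must have columns index, x, amplitude, curvature")
    msg <- character()
    if (nrow(p) > 1L && any(diff(p$x) <= 0))
      msg <- c(msg, "peak x positions must be strictly increasing")
    if (anyDuplicated(p$index))
      msg <- c(msg, "peak indices must be unique")
    if (length(msg)) msg else TRUE
  })

#' Decomposition: a fitted sum of line profiles
#'
#' `components` is a data.frame with one row per profile and columns
#' `family` ("gaussian", "lorentzian" or "voigt"), `center`, `amplitude`
#' (peak height), `sigma` (Gaussian width) and `gamma` (Lorentzian
#' half-width at half maximum). For pure Gaussians `gamma` is 0 and
#' ignored; for pure Lorentzians `sigma` is 0 and ignored.
#'
#' @slot components data.frame of per-profile parameters.
#' @slot loss robust loss used ("linear", "soft_l1", "huber", "arctan").
#' @slot cost final value of the robust objective.
#' @slot nIter optimizer iterations consumed.
#' @slot reconstruction model evaluated on the fitting grid.
#'
#' @aliases Decomposition-class
#' @exportClass Decomposition
setClass("Decomposition",
  representation(components = "data.frame", loss = "character",
                 cost = "numeric", nIter = "integer",
                 reconstruction = "numeric"),
  validity = function(object) {
    need <- c("family", "center", "amplitude", "sigma", "gamma")
    if (!all(need %in% names(object@components)))
      return("components must have columns family, center, amplitude, sigma, gamma")
    msg <- character()
    if (length(object@cost) != 1L || !is.finite(object@cost) || object@cost < 0)
      msg <- c(msg, "cost must be a single non-negative finite number")
    if (!all(is.finite(object@reconstruction)))
      msg <- c(msg, "reconstruction must be finite")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: the generating recipe for a synthetic spectrum
#'
#' @slot components data.frame of true profile parameters (same columns as
#'   [Decomposition-class] components).
#' @slot baselineSpec list with element `type` ("none", "affine",
#'   "multisine") and type-specific parameters.
#' @slot noiseSigma standard deviation of additive Gaussian noise (>= 0).
#' @slot seed integer PRNG seed; the same truth object always regenerates a
#'   bit-identical spectrum.
#'
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(components = "data.frame", baselineSpec = "list",
                 noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (!is.character(object@baselineSpec$type) ||
        !object@baselineSpec$type %in% c("none", "affine", "multisine"))
      msg <- c(msg, "baselineSpec$type must be none, affine or multisine")
    if (length(msg)) msg else TRUE
  })

#' Construct a GroundTruth object
#'
#' @param components data.frame with columns family, center, amplitude,
#'   sigma, gamma (one row per profile).
#' @param baselineSpec list(type = "none"/"affine"/"multisine", ...);
#'   affine takes `intercept` and `slope`, multisine takes vectors
#'   `amplitudes`, `periods` (in x units) and `phases`.
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @param seed integer seed controlling the noise draw.
#' @return A [GroundTruth-class] object.
#' @export
groundTruth <- function(components,
                        baselineSpec = list(type = "none"),
                        noiseSigma = 0, seed = 1L) {
  new("GroundTruth", components = as.data.frame(components),
      baselineSpec = baselineSpec, noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}
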