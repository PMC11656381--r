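# Synthetic spectra with known ground truth. All randomness goes through
# R's Mersenne-Twister with the truth object's seed, restored on exit,
# so a truth object always regenerates a bit-identical spectrum and the
# caller's RNG state is untouched.

.baselineEval <- function(spec, x) {
  switch(spec$type,
    none = numeric(length(x)),
    affine = spec$intercept + spec$slope * x,
    multisine = {
      b <- numeric(length(x))
      for (i in seq_along(spec$amplitudes))
        b <- b + spec$amplitudes[i] *
          sin(2 * pi * x / spec$periods[i] + spec$phases[i])
      b
    },
    stop("unknown baseline type: ", spec$type))
}

#' Render a ground-truth recipe into a spectrum
#'
#' y = modelSum(components) + baseline(x) + Gaussian noise(seed) on a
#' uniform grid of `nPoints` samples over [xMin, xMax].
#'
#' @param gt a [GroundTruth-class].
#' @param xMin,xMax grid limits.
#' @param nPoints number of samples (>= 16).
#' @param xLabel,yLabel axis labels.
#' @return list(spectrum = [Spectrum-class], truth = `gt`), the truth
#'   echoed for assertions against it.
#' @examples
#' gt <- groundTruth(data.frame(family = "gaussian", center = 5,
#'                              amplitude = 1, sigma = 0.5, gamma = 0))
#' makeSpectrum(gt, 0, 10, 256)$spectrum
#' @export
makeSpectrum <- function(gt, xMin, xMax, nPoints,
                         xLabel = "x", yLabel = "intensity") {
  stopifnot(is(gt, "GroundTruth"))
  nPoints <- as.integer(nPoints)
  if (is.na(nPoints) || nPoints < 16L)
    stop("nPoints must be >= 16")
  if (xMin >= xMax) stop("xMin must be < xMax")
  x <- seq(xMin, xMax, length.out = nPoints)
  y <- modelSum(gt@components, x) + .baselineEval(gt@baselineSpec, x)
  if (gt@noiseSigma > 0) {
    state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(state))
      assign(".Random.seed", state, globalenv())
      else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(gt@seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    y <- y + stats::rnorm(nPoints, sd = gt@noiseSigma)
  }
  list(spectrum = Spectrum(x, y, xLabel = xLabel, yLabel = yLabel),
       truth = gt)
}

#' Deterministic synthetic test families
#'
#' Versioned fixture suites emulating the classes of signal the engine
#' targets:
#' \describe{
#'   \item{fig1_multisine}{well-separated Gaussian peaks riding on a
#'     strong drift built from multiple sine functions -- the stress
#'     case for baseline correction, where the two PLS methods differ in
#'     amplitude but must not move peak positions.}
#'   \item{fig2_test}{a moderate five-peak signal (mixed widths, gentle
#'     affine drift, mild noise) for exercising the window-propagation
#'     detector across window/threshold settings.}
#'   \item{narrow_xrd}{diffraction-like patterns: many sharp Gaussian
#'     reflections (widths under 1 percent of the x span) on a flat
#'     background.}
#'   \item{broad_uvvis}{absorption-like signals: few broad, strongly
#'     overlapping Voigt/Gaussian bands (at least one pair closer than
#'     the sum of its widths) on a multisine drift.}
#' }
#' Every member is reproducible from its embedded seed.
#'
#' @param name suite name.
#' @param nPoints grid size for each member (default 2000).
#' @return list of list(spectrum, truth) pairs.
#' @export
makeSuite <- function(name = c("fig1_multisine", "fig2_test",
                               "narrow_xrd", "broad_uvvis"),
                      nPoints = 2000L) {
  name <- match.arg(name)
  cmp <- function(family, center, amplitude, width1, width2 = 0)
    data.frame(family = family, center = center, amplitude = amplitude,
               sigma = width1, gamma = width2)
  switch(name,
    fig1_multisine = {
      # peaks on an extreme multi-sine drift (x span 100)
      comps <- rbind(
        cmp("gaussian", 15, 1.0, 1.2),
        cmp("gaussian", 38, 0.8, 1.5),
        cmp("gaussian", 62, 1.2, 1.0),
        cmp("gaussian", 85, 0.6, 1.4))
      drift <- list(type = "multisine",
                    amplitudes = c(0.8, 0.5, 0.3),
                    periods = c(100, 55, 30),
                    phases = c(0.4, 1.1, 2.0))
      list(makeSpectrum(groundTruth(comps, drift, 0, 101L), 0, 100,
                        nPoints))
    },
    fig2_test = {
      comps <- rbind(
        cmp("gaussian", 12, 1.0, 0.8),
        cmp("gaussian", 30, 0.7, 1.2),
        cmp("gaussian", 48, 1.3, 0.9),
        cmp("gaussian", 66, 0.5, 1.1),
        cmp("gaussian", 84, 0.9, 0.7))
      list(
        makeSpectrum(groundTruth(comps, list(type = "none"), 0, 201L),
                     0, 100, nPoints),
        makeSpectrum(groundTruth(comps,
                                 list(type = "affine", intercept = 0.05,
                                      slope = 0.001),
                                 0.004, 202L),
                     0, 100, nPoints))
    },
    narrow_xrd = {
      centersA <- c(25.2, 36.9, 37.8, 48.0, 53.9, 55.1, 62.7, 68.8,
                    70.3, 75.1)
      compsA <- cmp("gaussian", centersA,
                    c(1.0, 0.35, 0.25, 0.3, 0.2, 0.2, 0.15, 0.12, 0.1,
                      0.12),
                    rep(0.12, length(centersA)))
      centersB <- c(22.5, 31.7, 45.4, 56.5, 66.2, 75.3, 84.0)
      compsB <- cmp("gaussian", centersB,
                    c(0.8, 1.0, 0.5, 0.4, 0.3, 0.25, 0.2),
                    rep(0.15, length(centersB)))
      list(
        makeSpectrum(groundTruth(compsA, list(type = "none"), 0, 301L),
                     20, 85, nPoints),
        makeSpectrum(groundTruth(compsB, list(type = "none"), 0, 302L),
                     15, 90, nPoints))
    },
    broad_uvvis = {
      # strongly overlapping broad bands; 575/614 separation (39 nm) is
      # below the sum of widths, mimicking pigment absorption shoulders
      comps <- rbind(
        cmp("gaussian", 480, 0.5, 28),
        cmp("gaussian", 575, 0.9, 24),
        cmp("gaussian", 614, 0.8, 22),
        cmp("gaussian", 679, 1.0, 20))
      drift <- list(type = "multisine",
                    amplitudes = c(0.15, 0.08),
                    periods = c(400, 150),
                    phases = c(0.7, 2.3))
      list(
        makeSpectrum(groundTruth(comps, drift, 0, 401L), 380, 780,
                     nPoints),
        makeSpectrum(groundTruth(comps, drift, 0.005, 402L), 380, 780,
                     nPoints))
    })
}
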