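#' Run the full analysis pipeline
#'
#' Executes the stages in their mandatory order -- interpolate ->
#' denoise -> baseline -> peak detection -> decomposition -- and writes
#' every artifact plus a manifest echoing the parameters, so a run can
#' be reproduced from the manifest alone. Stages can be disabled
#' (`interp = 0`, `denoiseWindow = 0`, `baselineMethod = "none"`,
#' `decompose = FALSE`); decomposition without detection is impossible
#' by construction since the fit consumes the detected peaks.
#'
#' Artifacts written to `outDir`: `detrended.txt` and `baseline.txt`
#' (two-column text), `peaks.tsv` (peak table), `decomposition.json`,
#' `reconstruction.txt`, `manifest.json`. On a stage failure the
#' partially written artifacts are removed and the error names the
#' stage.
#'
#' @param input path to a two-column text spectrum, or a
#'   [Spectrum-class].
#' @param outDir output directory (created if missing).
#' @param interp number of uniform-grid points (0 = keep the input grid,
#'   which must then already be uniform for the detector).
#' @param denoiseWindow moving-average window in samples; 0 or 1
#'   disables. May be a vector for consecutive passes (e.g.
#'   c(100, 30, 10)).
#' @param baselineMethod "arpls", "airpls", "linear" or "none".
#' @param lam,ratio,baselineMaxIter PLS baseline parameters.
#' @param windowSize,threshold,minAmplitude peak-detection parameters.
#' @param family,loss,maxIter decomposition parameters.
#' @param decompose run the decomposition stage (default TRUE).
#' @param xMin,xMax optional crop applied before interpolation.
#' @param verbose print per-stage summaries.
#' @return Invisibly, a list with the [Spectrum-class] objects and stage
#'   results (`spectrum`, `detrended`, `baseline`, `peaks`,
#'   `decomposition`, `manifest`).
#' @export
runPipeline <- function(input, outDir,
                        interp = 10000L,
                        denoiseWindow = 0L,
                        baselineMethod = c("arpls", "airpls", "linear",
                                           "none"),
                        lam = 200, ratio = 1e-6, baselineMaxIter = 50L,
                        windowSize = 10L, threshold = 0,
                        minAmplitude = 0,
                        family = c("lorentzian", "gaussian", "voigt"),
                        loss = c("soft_l1", "linear", "huber", "arctan"),
                        maxIter = 100L, decompose = TRUE,
                        xMin = NULL, xMax = NULL, verbose = FALSE) {
  baselineMethod <- match.arg(baselineMethod)
  family <- match.arg(family)
  loss <- match.arg(loss)
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  written <- character(0)
  emit <- function(fun, obj, file) {
    p <- file.path(outDir, file)
    fun(obj, p)
    written <<- c(written, p)
  }
  stage <- "input"
  tryCatch({
    s <- if (is(input, "Spectrum")) input else readSpectrum(input)
    if (!is.null(xMin) || !is.null(xMax)) {
      stage <- "crop"
      s <- crop(s, if (is.null(xMin)) s@x[1L] else xMin,
                if (is.null(xMax)) s@x[length(s@x)] else xMax)
    }
    stage <- "interpolate"
    if (interp >= 2L) s <- interpolateUniform(s, interp)
    stage <- "denoise"
    for (w in denoiseWindow)
      if (w > 1L) s <- denoise(s, w)
    stage <- "baseline"
    det <- detrend(s, baselineMethod, lam = lam, ratio = ratio,
                   maxIter = baselineMaxIter)
    bl <- det$baseline
    sHat <- det$spectrum
    emit(writeSpectrum, sHat, "detrended.txt")
    emit(writeSpectrum, initialize(s, y = bl@z), "baseline.txt")
    if (verbose)
      message("baseline [", baselineMethod, "]: ", bl@nIter,
              " iterations, converged = ", bl@converged)
    stage <- "peaks"
    pks <- detectPeaks(sHat, windowSize = windowSize,
                       threshold = threshold,
                       minAmplitude = minAmplitude)
    emit(writePeakTable, pks, "peaks.tsv")
    if (verbose) message("peaks: ", length(pks), " detected")
    dec <- NULL
    if (decompose) {
      stage <- "decompose"
      if (length(pks) < 1L)
        stop("no peaks detected; cannot decompose")
      dec <- fitDecomposition(sHat, pks, family = family, loss = loss,
                              maxIter = maxIter)
      emit(writeDecomposition, dec, "decomposition.json")
      emit(writeSpectrum, initialize(sHat, y = dec@reconstruction),
           "reconstruction.txt")
      if (verbose)
        message("decomposition [", family, "/", loss, "]: cost = ",
                format(dec@cost), " after ", dec@nIter, " iterations")
    }
    stage <- "manifest"
    manifest <- list(
      input = if (is.character(input)) input else "<in-memory spectrum>",
      xMin = xMin, xMax = xMax, interp = interp,
      denoiseWindow = denoiseWindow,
      baselineMethod = baselineMethod, lam = lam, ratio = ratio,
      baselineMaxIter = baselineMaxIter,
      windowSize = windowSize, threshold = threshold,
      minAmplitude = minAmplitude,
      family = family, loss = loss, maxIter = maxIter,
      decompose = decompose)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(spectrum = s, detrended = sHat, baseline = bl,
                   peaks = pks, decomposition = dec,
                   manifest = manifest))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
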