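#' Read a two-column spectrum from plain text
#'
#' Reads a text file whose first column is the abscissa (wavenumber,
#' wavelength or two-theta) and second column the intensity. Lines
#' starting with '#' and blank lines are skipped. The delimiter is
#' auto-detected among whitespace, comma and tab when not supplied.
#' Rows are sorted by x; exact duplicate x values are rejected.
#'
#' @param path path to the file.
#' @param delimiter optional single-character delimiter; default
#'   auto-detect.
#' @param xLabel,yLabel axis labels to attach.
#' @return A [Spectrum-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# wavenumber intensity", "3 15", "1 10", "2 20"), f)
#' readSpectrum(f)
#' @export
readSpectrum <- function(path, delimiter = NULL,
                         xLabel = "x", yLabel = "intensity") {
  if (!file.exists(path))
    stop("cannot read spectrum: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(delimiter)) {
    # prefer comma, then tab, then any whitespace
    delimiter <- if (any(grepl(",", lines, fixed = TRUE))) ","
                 else if (any(grepl("\t", lines, fixed = TRUE))) "\t"
                 else "[[:space:]]+"
  } else if (delimiter == " ") {
    delimiter <- "[[:space:]]+"
  }
  parts <- strsplit(lines, delimiter)
  keep <- vapply(parts, function(p) {
    p <- p[nzchar(p)]
    length(p) >= 2L && !anyNA(suppressWarnings(as.numeric(p[1:2])))
  }, logical(1L))
  parts <- parts[keep]
  if (length(parts) < 2L)
    stop("format error: fewer than 2 parseable numeric rows in ", path)
  xy <- t(vapply(parts, function(p) {
    p <- p[nzchar(p)]
    suppressWarnings(as.numeric(p[1:2]))
  }, numeric(2L)))
  Spectrum(xy[, 1L], xy[, 2L], xLabel = xLabel, yLabel = yLabel)
}

#' Write a spectrum as two-column text
#'
#' Full double precision ('%.9g' would truncate round-tripping, so 17
#' significant digits are used); the output is readable by
#' [readSpectrum()] with values equal within 1e-9 relative.
#'
#' @param s a [Spectrum-class].
#' @param path output path.
#' @param delimiter column separator (default single space).
#' @return Invisibly, `path`.
#' @export
writeSpectrum <- function(s, path, delimiter = " ") {
  stopifnot(is(s, "Spectrum"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write spectrum: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("# %s%s%s", s@xLabel, delimiter, s@yLabel), con)
  writeLines(paste(formatC(s@x, digits = 17, format = "g"),
                   formatC(s@y, digits = 17, format = "g"),
                   sep = delimiter), con)
  invisible(path)
}

#' Write a fitted peak table as TSV
#'
#' One row per fitted profile with columns
#' `center`, `amplitude`, `width1` (Gaussian sigma), `width2`
#' (Lorentzian half-width gamma) and `family`. An empty decomposition
#' writes a header-only table.
#'
#' @param d a [Decomposition-class] (or a [PeakSet-class], in which case
#'   columns are center, amplitude, width1 = NA, width2 = NA, family =
#'   "peak").
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePeakTable <- function(d, path) {
  if (is(d, "Decomposition")) {
    cmp <- d@components
    tab <- data.frame(center = cmp$center, amplitude = cmp$amplitude,
                      width1 = cmp$sigma, width2 = cmp$gamma,
                      family = cmp$family)
  } else if (is(d, "PeakSet")) {
    p <- d@peaks
    tab <- data.frame(center = p$x, amplitude = p$amplitude,
                      width1 = rep(NA_real_, nrow(p)),
                      width2 = rep(NA_real_, nrow(p)),
                      family = rep("peak", nrow(p)))
  } else stop("writePeakTable() expects a Decomposition or PeakSet")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalize a spectrum to unit maximum
#'
#' Scales y so that max(y) == 1; x is unchanged.
#'
#' @param s a [Spectrum-class] with max(abs(y)) > 0.
#' @return The normalized [Spectrum-class].
#' @examples
#' normalizeSpectrum(Spectrum(1:3, c(0, 2, 4)))
#' @export
normalizeSpectrum <- function(s) {
  stopifnot(is(s, "Spectrum"))
  m <- max(s@y)
  if (m <= 0)
    stop("degenerate input: maximum intensity must be positive to ",
         "normalize to unit maximum")
  initialize(s, y = s@y / m)
}

#' Crop a spectrum to a closed x interval
#'
#' @param s a [Spectrum-class].
#' @param xMin,xMax interval bounds, xMin < xMax; must intersect the
#'   spectrum's x values in at least 2 points.
#' @return The cropped [Spectrum-class].
#' @examples
#' crop(Spectrum(1:10, 1:10), 3, 5)
#' @export
crop <- function(s, xMin, xMax) {
  stopifnot(is(s, "Spectrum"))
  if (xMin >= xMax) stop("xMin must be < xMax")
  keep <- s@x >= xMin & s@x <= xMax
  if (!any(keep))
    stop("range error: [", xMin, ", ", xMax,
         "] does not intersect the spectrum's x range")
  if (sum(keep) < 2L)
    stop("range error: fewer than 2 points in [", xMin, ", ", xMax, "]")
  initialize(s, x = s@x[keep], y = s@y[keep])
}
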