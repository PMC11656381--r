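test_that("reader parses two-column text, sorts by x and skips comments", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 10", "2 20", "3 15"), f)
  s <- readSpectrum(f)
  expect_equal(xValues(s), c(1, 2, 3))
  expect_equal(intensity(s), c(10, 20, 15))

  writeLines(c("3 15", "1 10", "2 20"), f)
  s2 <- readSpectrum(f)
  expect_equal(xValues(s2), c(1, 2, 3))
  expect_equal(intensity(s2), c(10, 20, 15))

  writeLines(c("# wavenumber intensity", "", "1,10", "2,20", "3,15"), f)
  s3 <- readSpectrum(f)
  expect_equal(intensity(s3), c(10, 20, 15))

  writeLines(c("1\t10", "2\t20"), f)
  expect_equal(xValues(readSpectrum(f)), c(1, 2))
})

test_that("reader rejects unreadable, short and duplicate-x inputs", {
  expect_error(readSpectrum(file.path(tempdir(), "no-such-file.txt")),
               "not found")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only a header", "1 10"), f)
  expect_error(readSpectrum(f), "fewer than 2")
  writeLines(c("1 10", "2 20", "2 30"), f)
  expect_error(readSpectrum(f), "duplicate x value 2")
  expect_error(Spectrum(c(1, 1), c(0, 1)), "duplicate")
})

test_that("write/read round-trips spectra within 1e-9 relative", {
  withr::local_seed(11)
  f <- withr::local_tempfile(fileext = ".txt")
  for (i in 1:5) {
    n <- sample(10:200, 1)
    s <- Spectrum(sort(runif(n, -1e3, 1e3)) + seq_len(n) * 1e-6,
                  rnorm(n, sd = 10^runif(1, -3, 3)))
    writeSpectrum(s, f)
    r <- readSpectrum(f)
    expect_equal(xValues(r), xValues(s), tolerance = 1e-9)
    expect_equal(intensity(r), intensity(s), tolerance = 1e-9)
  }
})

test_that("normalization scales to unit maximum and is idempotent", {
  expect_equal(intensity(normalizeSpectrum(Spectrum(1:3, c(0, 2, 4)))),
               c(0, 0.5, 1))
  expect_equal(intensity(normalizeSpectrum(Spectrum(1:3, c(1, 1, 1)))),
               c(1, 1, 1))
  expect_equal(intensity(normalizeSpectrum(Spectrum(1:3, c(-1, 0, 2)))),
               c(-0.5, 0, 1))
  s <- Spectrum(1:50, rnorm(50) + 2)
  expect_equal(normalizeSpectrum(normalizeSpectrum(s)),
               normalizeSpectrum(s))
  expect_error(normalizeSpectrum(Spectrum(1:3, c(0, 0, 0))),
               "degenerate")
})

test_that("crop keeps the closed interval and nests", {
  s <- Spectrum(1:10, 11:20)
  expect_equal(xValues(crop(s, 3, 5)), c(3, 4, 5))
  expect_equal(crop(s, 1, 10), s)
  expect_error(crop(s, 100, 200), "range error")
  expect_error(crop(s, 5, 3), "xMin")
  # crop(a,b) then crop(c,d) with [c,d] inside [a,b] == crop(c,d)
  expect_equal(crop(crop(s, 2, 9), 4, 7), crop(s, 4, 7))
})

test_that("peak tables have one row per component plus a header", {
  d <- new("Decomposition",
           components = data.frame(family = c("gaussian", "lorentzian"),
                                   center = c(1, 2), amplitude = c(3, 4),
                                   sigma = c(0.5, 0), gamma = c(0, 0.7)),
           loss = "linear", cost = 0, nIter = 0L,
           reconstruction = numeric(0))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePeakTable(d, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("center", "amplitude", "width1", "width2",
                      "family"))
  # empty decomposition -> header only
  d0 <- new("Decomposition", components = d@components[0, ],
            loss = "linear", cost = 0, nIter = 0L,
            reconstruction = numeric(0))
  writePeakTable(d0, f)
  expect_equal(nrow(read.delim(f)), 0L)
})

test_that("Spectrum validity rejects non-finite and mismatched input", {
  expect_error(Spectrum(1:3, c(1, NA, 3)))
  expect_error(Spectrum(c(1, Inf, 3), 1:3))
  expect_error(Spectrum(1:3, 1:2), "equal length")
  expect_error(Spectrum(1, 1))
})
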