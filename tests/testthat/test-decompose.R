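threePeakTruth <- function(family) {
  data.frame(family = family, center = c(25, 50, 75),
             amplitude = c(1, 0.7, 0.9),
             sigma = switch(family, gaussian = c(2, 2.5, 1.8),
                            lorentzian = c(0, 0, 0),
                            voigt = c(2, 2.5, 1.8)),
             gamma = switch(family, gaussian = c(0, 0, 0),
                            lorentzian = c(1.5, 1, 2),
                            voigt = c(1.5, 1, 2)))
}

detectOn <- function(sp) detectPeaks(sp, 41, 0.02, 0.1)

test_that("noiseless fits recover truth for every profile family", {
  for (family in c("gaussian", "lorentzian", "voigt")) {
    tr <- threePeakTruth(family)
    sp <- makeSpectrum(groundTruth(tr), 0, 100, 2000)$spectrum
    h <- diff(xValues(sp))[1]
    pk <- detectOn(sp)
    expect_equal(length(pk), 3L, info = family)
    fit <- fitDecomposition(sp, pk, family, "linear", 200)
    cmp <- components(fit)
    expect_lt(max(abs(cmp$center - tr$center)), 1e-3 * h)
    expect_lt(max(abs(cmp$amplitude - tr$amplitude) / tr$amplitude),
              0.01)
    if (family != "lorentzian")
      expect_lt(max(abs(cmp$sigma - tr$sigma) / tr$sigma), 0.02)
    if (family != "gaussian")
      expect_lt(max(abs(cmp$gamma - tr$gamma) / tr$gamma), 0.02)
    expect_equal(fit@reconstruction,
                 modelSum(cmp, xValues(sp)))
  }
})

test_that("1% noise leaves fitted centers within half a grid step", {
  tr <- threePeakTruth("gaussian")
  clean <- makeSpectrum(groundTruth(tr), 0, 100, 2000)$spectrum
  noisy <- makeSpectrum(groundTruth(tr, noiseSigma = 0.01, seed = 7L),
                        0, 100, 2000)$spectrum
  h <- diff(xValues(noisy))[1]
  fit <- fitDecomposition(noisy, detectOn(clean), "gaussian", "linear",
                          200)
  expect_lt(max(abs(components(fit)$center - tr$center)), 0.5 * h)
})

test_that("warm starts are fixed points at the optimum and never regress", {
  tr <- threePeakTruth("gaussian")
  sp <- makeSpectrum(groundTruth(tr), 0, 100, 2000)$spectrum
  truthFit <- new("Decomposition", components = tr, loss = "linear",
                  cost = 0, nIter = 0L,
                  reconstruction = modelSum(tr, xValues(sp)))
  again <- fitDecomposition(sp, NULL, "gaussian", "linear", 50,
                            warmStart = truthFit)
  expect_lt(again@cost, 1e-10)
  expect_lt(max(abs(components(again)$center - tr$center)), 1e-6)
  expect_lt(max(abs(components(again)$sigma - tr$sigma)), 1e-6)

  # chained warm starts on noisy data: non-increasing cost sequence
  noisy <- makeSpectrum(groundTruth(tr, noiseSigma = 0.01, seed = 9L),
                        0, 100, 2000)$spectrum
  pk <- detectOn(sp)
  costs <- numeric(4)
  fit <- fitDecomposition(noisy, pk, "gaussian", "linear", 3)
  costs[1] <- fit@cost
  for (i in 2:4) {
    fit <- fitDecomposition(noisy, pk, "gaussian", "linear", 3,
                            warmStart = fit)
    costs[i] <- fit@cost
  }
  expect_true(all(diff(costs) <= 1e-12))
  # and the budget never returns something worse than its start
  init <- fitDecomposition(noisy, pk, "gaussian", "linear", 1)
  expect_lte(fit@cost, init@cost)
})

test_that("robust losses fit and a Voigt truth ranks its own family first", {
  tr <- threePeakTruth("voigt")
  sp <- makeSpectrum(groundTruth(tr), 0, 100, 2000)$spectrum
  pk <- detectOn(sp)
  cost <- sapply(c("voigt", "lorentzian", "gaussian"), function(f)
    fitDecomposition(sp, pk, f, "linear", 200)@cost)
  expect_lte(cost["voigt"], cost["lorentzian"])
  expect_lte(cost["voigt"], cost["gaussian"])

  # robust losses converge on noisy data and report their own objective
  noisy <- makeSpectrum(groundTruth(threePeakTruth("gaussian"),
                                    noiseSigma = 0.02, seed = 12L),
                        0, 100, 2000)$spectrum
  for (lo in c("soft_l1", "huber", "arctan")) {
    fit <- fitDecomposition(noisy, pk, "gaussian", lo, 100)
    expect_equal(fit@cost,
                 decompositionCost(components(fit), intensity(noisy),
                                   xValues(noisy), lo))
    expect_lt(max(abs(components(fit)$center - tr$center)), 0.5)
  }
})

test_that("a single pure Gaussian fit matches its moment estimates", {
  x <- seq(0, 40, length.out = 1500)
  y <- profileEval("gaussian", 17.3, 2.1, sigma = 1.4, x = x)
  sp <- Spectrum(x, y)
  fit <- fitDecomposition(sp, detectPeaks(sp, 51, 0.05, 0.1),
                          "gaussian", "linear", 100)
  cm <- sum(x * y) / sum(y)
  sm <- sqrt(sum((x - cm)^2 * y) / sum(y))
  cmp <- components(fit)
  expect_lt(abs(cmp$center - cm), 1e-4)
  expect_lt(abs(cmp$sigma - sm), 1e-3)
  expect_lt(abs(cmp$amplitude - 2.1), 1e-6)
})

test_that("decomposition JSON round-trips", {
  tr <- threePeakTruth("lorentzian")
  sp <- makeSpectrum(groundTruth(tr), 0, 100, 1000)$spectrum
  fit <- fitDecomposition(sp, detectOn(sp), "lorentzian", "soft_l1", 50)
  f <- withr::local_tempfile(fileext = ".json")
  writeDecomposition(fit, f)
  back <- readDecomposition(f)
  expect_equal(components(back), components(fit), tolerance = 1e-12)
  expect_equal(back@loss, "soft_l1")
  expect_equal(back@cost, fit@cost, tolerance = 1e-12)
})
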