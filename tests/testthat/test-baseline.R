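test_that("difference matrix has (1,-2,1) rows annihilating affine vectors", {
  D <- differenceMatrix(4, sparse = FALSE)
  expect_equal(dim(D), c(2L, 4L))
  expect_equal(D[1, ], c(1, -2, 1, 0))
  expect_equal(D[2, ], c(0, 1, -2, 1))
  D9 <- differenceMatrix(9)
  expect_equal(as.numeric(D9 %*% rep(3.7, 9)), rep(0, 7))
  expect_equal(as.numeric(D9 %*% (2 + 0.5 * (1:9))), rep(0, 7))
  expect_error(differenceMatrix(2), ">= 3")
})

test_that("linear baseline is the chord through the endpoints", {
  s <- Spectrum(0:2, c(0, 5, 0))
  r <- linearBaseline(s)
  expect_equal(baselineVector(r), c(0, 0, 0))
  expect_equal(intensity(s) - baselineVector(r), c(0, 5, 0))

  s2 <- Spectrum(0:2, c(1, 9, 3))
  expect_equal(baselineVector(linearBaseline(s2)), c(1, 2, 3))

  # affine signal detrends to zero
  s3 <- Spectrum(seq(0, 5, by = 0.5), 2 - 3 * seq(0, 5, by = 0.5))
  expect_equal(intensity(s3) - baselineVector(linearBaseline(s3)),
               rep(0, length(s3)))
})

test_that("sparse PLS solve matches a dense direct solve", {
  withr::local_seed(21)
  for (i in 1:5) {
    n <- sample(10:200, 1)
    s <- rnorm(n)
    w <- runif(n)
    lam <- 10^runif(1, -1, 4)
    expect_lt(max(abs(plsSolve(s, w, lam) - densePlsSolve(s, w, lam))),
              1e-8)
  }
})

test_that("PLS limits: data-faithful at small lambda, straight line at large", {
  withr::local_seed(22)
  n <- 100
  s <- rnorm(n, sd = 2)
  w <- rep(1, n)
  expect_lt(max(abs(plsSolve(s, w, 1e-12) - s)), 1e-6)
  # lambda -> Inf collapses onto the least-squares straight line
  x <- seq_len(n)
  line <- as.numeric(cbind(1, x) %*% coef(lm.fit(cbind(1, x), s)))
  expect_lt(max(abs(plsSolve(s, w, 1e12) - line)), 1e-4)
  # affine inputs are exact fixed points at any lambda and weights
  aff <- 0.3 + 0.1 * x
  expect_lt(max(abs(plsSolve(aff, runif(n, 0.1, 1), 50) - aff)), 1e-8)
  # shifting the data by a constant shifts the solution by the same
  z1 <- plsSolve(s, w, 10)
  expect_lt(max(abs(plsSolve(s + 4.2, w, 10) - (z1 + 4.2))), 1e-8)
})

test_that("airPLS matches an independent dense reference and its weight rule", {
  withr::local_seed(23)
  x <- seq(0, 30, length.out = 120)
  s <- exp(-(x - 10)^2 / 2) + 0.5 * exp(-(x - 22)^2 / 1.5) +
    0.02 * x + 0.2
  r <- airPLS(s, lam = 100, ratio = 1e-6, maxIter = 30)
  zref <- refAirPLS(s, lam = 100, ratio = 1e-6, maxIter = 30)
  expect_lt(max(abs(baselineVector(r) - zref)), 1e-8)

  # constant signal is its own baseline
  rc <- airPLS(rep(2, 50), lam = 100)
  expect_lt(max(abs(baselineVector(rc) - 2)), 1e-6)

  # after iteration 1 the weights vanish exactly above the baseline
  # (interior points; the first and last weight are anchored > 0 by the
  # reference update rule)
  r1 <- airPLS(s, lam = 100, ratio = 1e-12, maxIter = 1)
  d <- s - baselineVector(r1)
  interior <- 2:(length(s) - 1)
  expect_true(all(r1@weights[interior][d[interior] >= 0] == 0))
  expect_true(all(r1@weights[interior][d[interior] < 0] > 0))

  # single bump on zero background: baseline stays under 5% of height
  sb <- exp(-(x - 15)^2 / 4)
  rb <- airPLS(sb, lam = 1000, maxIter = 30)
  expect_lt(max(abs(baselineVector(rb))), 0.05)
  expect_lte(rb@nIter, 30L)
})

test_that("arPLS matches its dense reference and behaves asymmetrically", {
  x <- seq(0, 30, length.out = 150)
  s <- exp(-(x - 8)^2 / 2) + 0.8 * exp(-(x - 16)^2 / 3) +
    0.6 * exp(-(x - 24)^2 / 2) + 0.3 * sin(x / 4)
  r <- arPLS(s, lam = 1e4, ratio = 1e-6, maxIter = 30)
  zref <- refArPLS(s, lam = 1e4, ratio = 1e-6, maxIter = 30)
  expect_lt(max(abs(baselineVector(r) - zref)), 1e-8)
  expect_true(all(r@weights >= 0 & r@weights <= 1))
  expect_true(all(is.finite(baselineVector(r))))

  # constant signal: near-degenerate residuals, detrended ~ 0
  rc <- arPLS(rep(3, 60), lam = 100)
  expect_lt(max(abs(baselineVector(rc) - 3)), 1e-6)
  expect_true(rc@converged)

  # the logistic weight is monotone non-increasing in the residual, so
  # samples far above the baseline (peaks) are down-weighted
  d <- seq(-2, 5, by = 0.01)
  w <- specdecon:::arplsWeights(d, m = -0.1, sg = 0.2)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("detrend dispatches, disables and preserves peak positions", {
  s <- makeSuite("fig2_test")[[1]]$spectrum
  none <- detrend(s, "none")
  expect_equal(none$spectrum, s)
  expect_true(all(baselineVector(none$baseline) == 0))

  aff <- Spectrum(1:50, 2 + 0.3 * (1:50))
  lin <- detrend(aff, "linear")
  expect_equal(intensity(lin$spectrum), rep(0, 50))

  # the two PLS corrections change amplitudes, not argmax positions
  m <- makeSuite("fig1_multisine")[[1]]
  h <- diff(xValues(m$spectrum))[1]
  air <- detrend(m$spectrum, "airpls", lam = 1e6)$spectrum
  arp <- detrend(m$spectrum, "arpls", lam = 1e6)$spectrum
  for (ct in m$truth@components$center) {
    win <- which(abs(xValues(m$spectrum) - ct) < 5)
    pa <- xValues(air)[win[which.max(intensity(air)[win])]]
    pr <- xValues(arp)[win[which.max(intensity(arp)[win])]]
    expect_lte(abs(pa - pr), h + 1e-12)
  }
})
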