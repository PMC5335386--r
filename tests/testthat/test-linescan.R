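test_that("profile extraction subtracts the pre-puff baseline", {
  ## constant field with an offset: profiles vanish after subtraction
  m <- matrix(7, 50, 1000)
  k <- kymograph(m, pixelUm = 0.2, puffLine = 200)
  pr <- extractProfiles(k)
  expect_true(all(pr$profiles == 0))

  ## cadence: 150 ms at 625 Hz is ~94 lines
  expect_equal(diff(pr$timeS)[1] * 625, 94, tolerance = 0.5)

  expect_error(extractProfiles(kymograph(m, 0.2, puffLine = 1)),
               "baseline")
})

test_that("Gaussian profile fits recover widths", {
  x <- seq(0, 50, by = 0.25)
  y <- 10 * exp(-(x - 25)^2 / 2^2) + 1
  g <- fitGaussianProfile(x, y)
  expect_true(g$converged)
  expect_equal(g$gamma, 2, tolerance = 1e-6)
  expect_equal(g$A, 10, tolerance = 1e-6)

  set.seed(11)
  errs <- replicate(30, {
    yp <- rpois(length(x), 1000 * exp(-(x - 25)^2 / 5^2) + 10)
    fitGaussianProfile(x, yp)$gamma / 5 - 1
  })
  expect_lt(median(abs(errs)), 0.02)

  flat <- fitGaussianProfile(x, rep(3, length(x)))
  expect_false(flat$converged)
})

test_that("width regression yields the diffusion coefficient", {
  tS <- seq(0.15, 2, by = 0.15)
  gam <- sqrt(4 * 0.5 * tS * 1000)       # gamma^2 = 4 D t, D = 0.5 um^2/ms
  est <- estimateDiffusionCoefficient(data.frame(timeS = tS, gamma = gam))
  expect_equal(est$D, 0.5, tolerance = 1e-9)
  expect_equal(est$r2, 1)

  cst <- suppressWarnings(estimateDiffusionCoefficient(
    data.frame(timeS = tS, gamma = rep(3, length(tS)))))
  expect_equal(cst$D, 0, tolerance = 1e-9)

  expect_error(estimateDiffusionCoefficient(
    data.frame(timeS = c(0.1, 0.2), gamma = c(1, 2))), "at least 3")
})

test_that("tortuosity and hydrodynamic diameter follow their closed forms", {
  expect_equal(tortuosity(0.4, 0.4), 1)
  expect_equal(tortuosity(0.51, 0.38), sqrt(0.51 / 0.38))
  expect_equal(round(tortuosity(0.51, 0.38), 1), 1.2)
  expect_equal(tortuosity(0.49, 0.17), 1.6977, tolerance = 1e-4)
  expect_warning(tortuosity(0.38, 0.44), "< 1")
  ## monotone decreasing in the apparent coefficient
  ds <- seq(0.1, 0.5, by = 0.1)
  expect_true(all(diff(suppressWarnings(
    vapply(ds, function(d) tortuosity(0.3, d), 0))) < 0))

  expect_equal(hydrodynamicDiameter(0.38), 1.1745, tolerance = 1e-3)
  expect_equal(hydrodynamicDiameter(0.51), 0.8751, tolerance = 1e-3)
  expect_equal(hydrodynamicDiameter(0.2) * 0.2,
               hydrodynamicDiameter(0.4) * 0.4)
})

test_that("the pipeline recovers the generating coefficient end to end", {
  for (D0 in c(0.2, 0.45)) {
    syn <- synthKymograph(synthSpec(kymoD = D0), seed = 21)
    est <- analyzeKymograph(syn$kymo)
    expect_lt(abs(est$D / D0 - 1), 0.05)
  }
  ## noiseless widths follow gamma^2 = 4 D t exactly
  syn <- synthKymograph(synthSpec(kymoD = 0.3, kymoPeakCounts = Inf))
  est <- analyzeKymograph(syn$kymo)
  expect_equal(est$D, 0.3, tolerance = 1e-6)
  pf <- est$profileFits
  expect_lt(max(abs(pf$gamma^2 / (4 * 0.3 * pf$timeS * 1000) - 1)), 1e-6)
})

test_that("kymograph CSV interchange round-trips", {
  syn <- synthKymograph(synthSpec(kymoD = 0.3, kymoNx = 60L,
                                  kymoDurationS = 1), seed = 2)
  f <- tempfile(fileext = ".csv")
  writeKymographCSV(syn$kymo, f)
  back <- readKymographCSV(f)
  expect_equal(back@intensity, syn$kymo@intensity)
  expect_equal(back@lineRateHz, 625)
  expect_equal(back@puffLine, syn$kymo@puffLine)
})
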