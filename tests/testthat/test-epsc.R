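twoStateScheme <- function(kon = 1e6, koff = 500) {
  kineticScheme(
    c("C", "O"),
    data.frame(from = c("C", "O"), to = c("O", "C"), rate = c(kon, koff),
               ligand = c("Glu", NA), effect = c("consume", "release")),
    conducting = "O")
}

competitiveScheme <- function(kon = 1e6, koff = 500, konB = 1e6,
                              koffB = 500) {
  kineticScheme(
    c("C", "CG", "CB"),
    data.frame(from = c("C", "CG", "C", "CB"), to = c("CG", "C", "CB", "C"),
               rate = c(kon, koff, konB, koffB),
               ligand = c("Glu", NA, "Ant", NA),
               effect = c("consume", "release", "consume", "release")),
    conducting = "CG")
}

test_that("trivial transients give trivial responses", {
  sch <- ampaSchemeGeneric()
  cfg <- epscConfig(spanMs = 10)
  z <- simulateEPSC(sch, glutTransient(0, 1), config = cfg)
  expect_equal(max(abs(z$open)), 0)
  expect_equal(blockRatio(sch, glutTransient(1e-3, 1.2), 0, cfg), 1)
  expect_error(blockRatio(sch, glutTransient(0, 1), 1e-4, cfg), "zero")
})

test_that("occupancies are conserved and obey closed forms", {
  sch <- twoStateScheme()
  L <- 2e-4
  ## near-constant ligand: steady state occupancy kon L / (kon L + koff)
  cfg <- epscConfig(spanMs = 50, outputMs = 0.1)
  res <- simulateEPSC(sch, glutTransient(L, 1e9), config = cfg)
  expect_lt(res$maxLeak, 1e-9)
  expect_equal(res$peak, 1e6 * L / (1e6 * L + 500), tolerance = 1e-4)
  ## driving force scaling
  expect_equal(res$current, res$open * -70)
})

test_that("integration converges at the default step size", {
  sch <- ampaSchemeGeneric()
  tr <- glutTransient(1e-3, 1.2)
  p5 <- simulateEPSC(sch, tr, 3e-4, epscConfig(stepUs = 5, spanMs = 15))$peak
  p2 <- simulateEPSC(sch, tr, 3e-4,
                     epscConfig(stepUs = 2.5, spanMs = 15))$peak
  expect_lt(abs(p5 / p2 - 1), 0.001)
})

test_that("slow-transient block matches the equilibrium competitive form", {
  sch <- competitiveScheme()
  KL <- 500 / 1e6; KB <- 500 / 1e6
  L <- 1e-4; B <- 3e-4
  br <- blockRatio(sch, glutTransient(L, 1e6),  # effectively constant
                   B, epscConfig(stepUs = 5, spanMs = 4000, outputMs = 1))
  closed <- (1 + L / KL) / (1 + L / KL + B / KB)
  expect_lt(abs(br / closed - 1), 0.02)
})

test_that("block deepens with antagonist and weakens with the transient", {
  sch <- ampaSchemeGeneric()
  cfg <- epscConfig(spanMs = 15)
  tr <- glutTransient(5e-4, 1.2)
  b <- vapply(c(0, 1e-4, 3e-4, 1e-3),
              function(B) blockRatio(sch, tr, B, cfg), 0)
  expect_true(all(diff(b) < 0))
  expect_equal(b[1], 1)
  ## larger transient peaks escape a competitive antagonist
  bp <- vapply(c(1e-4, 3e-4, 1e-3, 3e-3),
               function(p) blockRatio(sch, glutTransient(p, 1.2), 3e-4,
                                      cfg), 0)
  expect_true(all(diff(bp) > 0))
})

test_that("the block contour is monotone along both axes", {
  sch <- ampaSchemeGeneric()
  cfg <- epscConfig(spanMs = 12, outputMs = 0.05)
  peaks <- 10^seq(log10(5e-5), log10(3e-3), length.out = 10)
  taus <- 10^seq(log10(0.2), log10(4), length.out = 10)
  ctr <- blockContour(sch, peaks, taus, 3e-4, cfg)
  expect_identical(dim(ctr), c(10L, 10L))
  expect_true(all(apply(ctr, 2, diff) > -1e-6))
  expect_true(all(apply(ctr, 1, diff) > -1e-6))
  expect_true(all(ctr > 0 & ctr <= 1))
  ## single-point grid reduces to blockRatio
  one <- blockContour(sch, peaks[3], taus[3], 3e-4, cfg)
  expect_equal(one[1, 1],
               blockRatio(sch, glutTransient(peaks[3], taus[3]), 3e-4, cfg))
  ## the experimentally observed block level is attainable on the grid
  iso <- isoBlockLevel(ctr, 0.29)
  expect_gt(sum(is.finite(iso$peakM)), 0)
})

test_that("train summation reflects desensitization", {
  ## without desensitization and long intervals the train is flat
  flat <- simulateTrain(twoStateScheme(), glutTransient(2e-4, 1), 5, 100)
  expect_equal(flat$summationIndex, 1, tolerance = 0.01)
  expect_length(flat$pulsePeaks, 5L)

  ## no recovery between pulses: second peak below the first
  noRec <- ampaSchemeGeneric(kRes = 1e-9)
  tr2 <- simulateTrain(noRec, glutTransient(1e-3, 1.2), 2, 50)
  expect_lt(tr2$pulsePeaks[2], tr2$pulsePeaks[1])

  ## smaller transients desensitize less, so they sum closer to unity
  sch <- ampaSchemeGeneric()
  siSmall <- simulateTrain(sch, glutTransient(2e-4, 1.2), 5, 100)
  siLarge <- simulateTrain(sch, glutTransient(3e-3, 1.2), 5, 100)
  expect_gt(siSmall$summationIndex, siLarge$summationIndex)
})

test_that("antagonist use requires antagonist-binding states", {
  expect_error(simulateEPSC(twoStateScheme(), glutTransient(1e-4, 1), 1e-4),
               "no antagonist-binding")
})
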