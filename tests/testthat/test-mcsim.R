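test_that("free Brownian propagation recovers the diffusion coefficient", {
  d <- estimateFreeDiffusionD(0.33, nParticles = 4000, nSteps = 400,
                              seed = 1)
  expect_lt(abs(d / 0.33 - 1), 0.03)
  expect_equal(as.numeric(estimateFreeDiffusionD(0, nParticles = 100,
                                                 nSteps = 10)), 0)
})

test_that("inert scenes produce no reactions and conserve particles", {
  sc <- buildScene(sceneSpec("control", transporterDensity = 0))
  r <- runSimulation(sc, list(GLT = transporterQ10()), quickConfig(),
                     seed = 2)
  expect_true(all(r@cumulative == 0))
  expect_true(all(r@counts$bound == 0 & r@counts$translocated == 0))
  tot <- rowSums(r@counts)
  expect_true(all(tot == 200))
  ## particles exchange between cleft and neuropil only
  expect_gt(max(r@counts$freeExtra), 0)
})

test_that("simulation is bit-deterministic per seed and varies across seeds", {
  sc <- buildScene(sceneSpec("control"), edge = 0.03)
  sch <- list(GLT = transporterQ10())
  a <- runSimulation(sc, sch, quickConfig(), seed = 9)
  b <- runSimulation(sc, sch, quickConfig(), seed = 9)
  expect_identical(a@counts, b@counts)
  expect_identical(a@cumulative, b@cumulative)
  expect_identical(attr(a, "finalPos"), attr(b, "finalPos"))
  c3 <- runSimulation(sc, sch, quickConfig(), seed = 10)
  expect_false(identical(a@counts, c3@counts))
})

test_that("reactions obey conservation and tally ordering", {
  sc <- buildScene(sceneSpec("control"))
  r <- runSimulation(sc, list(GLT = transporterQ10()),
                     simConfig(nIterations = 1500, nMolecules = 500),
                     seed = 3)
  expect_true(all(rowSums(r@counts) == 500))
  expect_gt(max(r@cumulative$binding), 0)
  with(r@cumulative, {
    expect_true(all(binding >= unbinding + translocation))
    expect_true(all(diff(binding) >= 0))
    expect_true(all(diff(translocation) >= 0))
  })
  ## no free particle ends up inside a solid compartment
  expect_identical(auditParticlePositions(r, sc), 0L)
})

test_that("bimolecular binding matches the well-mixed kinetics oracle", {
  ## sealed box, no translocation: stochastic binding vs mass-action ODE
  density <- 2000
  sc <- calibrationBoxScene(edge = 1, density = density, seed = 1)
  params <- transporterParams(kTrans = 1e-9)
  sch <- list(GLT = transporterScheme(params, applyQ10 = TRUE))
  cfg <- simConfig(nIterations = 800, nMolecules = 1000,
                   releaseMode = "uniform", recordStride = 4)
  runs <- runSeeds(sc, sch, cfg, seeds = 1:3)
  mc <- rowMeans(vapply(runs, function(r) r@counts$bound,
                        numeric(length(runs[[1]]@time))))
  ode <- wellMixedBindingODE(
    kOn = q10Scale(params$kOn, 3, 25, 35),
    kOff = q10Scale(params$kOff, 3, 25, 35),
    nSites = round(density * 6), nLigand = 1000, volumeUm3 = 1,
    tMaxMs = 8, dtMs = 0.005)
  odeAt <- approx(ode$time, ode$bound, xout = runs[[1]]@time)$y
  rms <- sqrt(mean((mc - odeAt)^2)) / max(odeAt)
  expect_lt(rms, 0.05)
})

test_that("overly aggressive binding probabilities are rejected", {
  sc <- calibrationBoxScene(density = 100)
  sch <- list(GLT = transporterScheme(transporterParams(kOn = 1e12)))
  expect_error(runSimulation(sc, sch, quickConfig(releaseMode = "uniform")),
               "probability exceeds 1")
})

test_that("seed aggregation computes pointwise mean and SEM", {
  sc <- buildScene(sceneSpec("control"), edge = 0.03)
  sch <- list(GLT = transporterQ10())
  runs <- runSeeds(sc, sch, quickConfig(), seeds = 1:4)
  agg <- aggregateSeeds(runs)
  expect_equal(agg@nSeeds, 4)
  mat <- vapply(runs, function(r) r@counts$freeCleft,
                numeric(length(runs[[1]]@time)))
  expect_equal(agg@mean$freeCleft, rowMeans(mat))
  expect_equal(agg@sem$freeCleft, apply(mat, 1, sd) / 2)

  ## identical inputs: mean equals the input, SEM 0
  agg2 <- aggregateSeeds(list(runs[[1]], runs[[1]]))
  expect_equal(agg2@mean$freeCleft, runs[[1]]@counts$freeCleft)
  expect_true(all(agg2@sem == 0))

  expect_warning(agg1 <- aggregateSeeds(runs[1]), "single seed")
  expect_true(all(agg1@sem == 0))

  other <- runSimulation(buildScene(sceneSpec("tfllr"), edge = 0.03), sch,
                         quickConfig(), seed = 1)
  expect_error(aggregateSeeds(list(runs[[1]], other)), "hash")
})

test_that("SEM tracks sampling theory on synthetic series", {
  set.seed(42)
  n <- 300; len <- 20; sigma <- 3
  tmpl <- runSimulation(buildScene(sceneSpec("control", nAstro = 0),
                                   edge = 0.05),
                        list(GLT = transporterQ10()),
                        simConfig(nIterations = len - 1, nMolecules = 10,
                                  recordStride = 1), seed = 1)
  fakes <- lapply(seq_len(n), function(i) {
    r <- tmpl
    cnt <- r@counts
    cnt$freeExtra <- round(100 + rnorm(len, sd = sigma))
    cnt$freeCleft <- r@nMolecules - cnt$freeExtra - cnt$bound -
      cnt$translocated
    r@counts <- cnt
    r
  })
  agg <- aggregateSeeds(fakes)
  expect_lt(abs(mean(agg@sem$freeExtra) / (sigma / sqrt(n)) - 1), 0.1)
})

test_that("counts convert to molar concentrations", {
  sc <- buildScene(sceneSpec("control", nAstro = 0), edge = 0.05)
  r <- runSimulation(sc, list(GLT = transporterQ10()),
                     simConfig(nIterations = 10, nMolecules = 2000),
                     seed = 1)
  ## all 2000 molecules start in the cleft cylinder
  vol <- pi * sc@cleft$radius^2 * (sc@cleft$zmax - sc@cleft$zmin)  # um^3
  conc <- concentrationTimecourse(r, vol, "freeCleft")
  expect_equal(conc[1], 2000 / (6.02214076e23 * vol * 1e-15))
  expect_equal(signif(conc[1], 2), 1.7e-3)   # ~1.7 mM
  expect_equal(concentrationTimecourse(r, 2 * vol)[1], conc[1] / 2)
  cnt <- r@counts
  cnt$freeExtra <- cnt$freeExtra + cnt$freeCleft
  cnt$freeCleft <- 0L
  r@counts <- cnt
  expect_true(all(concentrationTimecourse(r, vol, "freeCleft") == 0))
})
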