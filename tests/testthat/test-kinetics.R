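test_that("Q10 scaling follows the exponential law and inverts", {
  expect_equal(q10Scale(2000, 3, 25, 35), 6000)
  expect_equal(q10Scale(123, 3, 25, 25), 123)
  expect_equal(q10Scale(50, 3, 25, 30), 50 * sqrt(3))
  set.seed(1)
  for (i in 1:20) {
    k <- runif(1, 1, 1e7); q <- runif(1, 1, 4)
    a <- runif(1, 15, 40); b <- runif(1, 15, 40)
    expect_equal(q10Scale(q10Scale(k, q, a, b), q, b, a), k)
    expect_equal(q10Scale(k, q, a, b) * q10Scale(1, q, b, a), k)
  }
})

test_that("the transporter scheme carries the stated rates", {
  sch <- transporterScheme(transporterParams(), applyQ10 = FALSE)
  tr <- sch@transitions
  expect_setequal(sch@states, c("T", "TG", "Tin"))
  expect_equal(tr$rate[tr$from == "T" & tr$to == "TG"], 6e6)
  expect_equal(tr$rate[tr$from == "TG" & tr$to == "T"], 601)
  expect_equal(tr$rate[tr$from == "TG" & tr$to == "Tin"], 2000)
  expect_equal(tr$rate[tr$from == "Tin" & tr$to == "T"], 50)
  expect_identical(tr$effect[tr$from == "TG" & tr$to == "Tin"], "sequester")

  scaled <- transporterScheme(transporterParams(), applyQ10 = TRUE)
  expect_equal(scaled@transitions$rate, tr$rate * 3)

  red <- transporterScheme(transporterParams(kTrans = 0))
  expect_false(any(red@transitions$from == "TG" &
                     red@transitions$to == "Tin"))
})

test_that("the apparent affinity is the cyclic steady-state value", {
  expect_equal(apparentKm(), (601 + 2000) * 50 / (6e6 * (50 + 2000)))
  expect_equal(apparentKm() * 1e6, 10.57317, tolerance = 1e-6)
  ## without translocation it reduces to the dissociation constant
  expect_equal(apparentKm(transporterParams(kTrans = 1e-12)), 601 / 6e6,
               tolerance = 1e-6)
  expect_equal(apparentKm(transporterParams(kOn = 1.2e7)),
               apparentKm() / 2)
})

test_that("well-mixed propagation matches closed forms and conserves mass", {
  twoState <- kineticScheme(
    c("C", "O"),
    data.frame(from = c("C", "O"), to = c("O", "C"), rate = c(1e6, 500),
               ligand = c("Glu", NA), effect = c("consume", "release")))
  L <- 2e-4
  occ <- integrateWellMixed(twoState, L, dt = 1e-6, nSteps = 20000)
  expect_equal(unname(occ[nrow(occ), "O"]), 1e6 * L / (1e6 * L + 500),
               tolerance = 1e-6)
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)

  ## zero ligand: the transporter stays outward-free
  sch <- transporterScheme()
  occ0 <- integrateWellMixed(sch, 0, dt = 1e-5, nSteps = 1000)
  expect_equal(unname(occ0[nrow(occ0), ]), c(1, 0, 0))

  expect_error(integrateWellMixed(twoState, 1e-2, dt = 1, nSteps = 10),
               "dt too large")
})

test_that("constant-ligand propagation matches the matrix exponential", {
  sch <- transporterScheme()
  L <- 5e-5
  dt <- 2e-6; nSteps <- 5000
  occ <- integrateWellMixed(sch, L, dt = dt, nSteps = nSteps)
  Q <- GluClear:::schemeGenerator(sch, L)
  pT <- as.numeric(c(1, 0, 0) %*%
                     as.matrix(Matrix::expm(Q * dt * nSteps)))
  expect_lt(max(abs(occ[nrow(occ), ] - pT)), 1e-6)
})

test_that("steady-state cycle flux is hyperbolic with the derived Km", {
  p <- transporterParams()
  km <- apparentKm(p)
  vmax <- transporterCycleFlux(p, 1)      # saturating glutamate
  ## half-saturation exactly at the derived Km
  expect_equal(transporterCycleFlux(p, km), vmax / 2, tolerance = 1e-3)
  ## hyperbolic over a 100-fold range
  ligands <- km * c(0.1, 0.2, 0.5, 1, 2, 3, 5, 7, 10)
  flux <- transporterCycleFlux(p, ligands)
  pred <- vmax * ligands / (ligands + km)
  expect_lt(max(abs(flux / pred - 1)), 1e-4)
})

test_that("scheme files round-trip and are schema-checked", {
  f <- tempfile(fileext = ".yaml")
  sch <- ampaSchemeGeneric()
  writeKineticScheme(sch, f)
  back <- readKineticScheme(f)
  expect_identical(back@states, sch@states)
  expect_equal(back@transitions$rate, sch@transitions$rate)
  expect_identical(back@conducting, "O")

  writeLines(c("states: [A]", "transitions: []", "mystery: 1"), f)
  expect_error(readKineticScheme(f), "mystery")

  glt <- readKineticScheme(system.file("extdata", "transporter_glt.yaml",
                                       package = "GluClear"))
  expect_equal(sort(glt@transitions$rate), c(50, 601, 2000, 6e6))
})

test_that("scheme validity rejects broken graphs and rates", {
  expect_error(kineticScheme(
    c("A", "B", "C"),
    data.frame(from = "A", to = "B", rate = 1, ligand = NA,
               effect = "none")), "not connected")
  expect_error(kineticScheme(
    c("A", "B"),
    data.frame(from = "A", to = "B", rate = -5, ligand = NA,
               effect = "none")), ">= 0")
})
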