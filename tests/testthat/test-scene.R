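test_that("control scene realises the specified geometry", {
  sc <- buildScene(sceneSpec("control"), seed = 1)
  expect_lt(abs(sceneAstroArea(sc) / 1.38 - 1), 0.01)
  expect_lt(abs(meshVolume(sc@meshes$presynaptic) / 0.079 - 1), 0.01)
  expect_lt(abs(meshVolume(sc@meshes$postsynaptic) / 0.040 - 1), 0.01)
  expect_lt(abs(meshArea(sc@meshes$PSD) / 0.10 - 1), 0.01)
  d <- nearestSurfaceDistance(sc@meshes$PSD, sc@meshes$astrocyte_1)
  expect_lt(abs(d - 116), 2)                  # nm
  ## everything inside the world box
  for (m in sc@meshes)
    expect_true(all(abs(m@vertices) <= 0.5 + 1e-9))
  ## transporter count = round(density * measured mesh area), per process
  for (k in 1:2) {
    pop <- sc@populations[[paste0("GLT_", k)]]
    hostArea <- meshArea(sc@meshes[[paste0("astrocyte_", k)]])
    expect_identical(nrow(pop@positions),
                     as.integer(round(10800 * hostArea)))
  }
})

test_that("the PAR1-activated scene has 4 farther, smaller processes", {
  sc <- buildScene(sceneSpec("tfllr"), seed = 1)
  astro <- grep("^astrocyte_", names(sc@meshes), value = TRUE)
  expect_length(astro, 4L)
  expect_lt(abs(sceneAstroArea(sc) / (4 * 0.54) - 1), 0.01)
  for (nm in astro) {
    d <- nearestSurfaceDistance(sc@meshes$PSD, sc@meshes[[nm]])
    expect_lt(abs(d - 190), 2)
  }
})

test_that("a scene without astrocytic processes is valid", {
  sc <- buildScene(sceneSpec("control", nAstro = 0), seed = 1)
  expect_length(grep("^astrocyte", names(sc@meshes)), 0L)
  expect_length(sc@populations, 0L)
})

test_that("infeasible packings raise geometric-feasibility errors", {
  expect_error(buildScene(sceneSpec("control", astroDistance = 600)),
               "infeasible")
  expect_error(buildScene(sceneSpec("control", astroDistance = 5)),
               "infeasible")   # sheets intersect the terminals
})

test_that("scene build is deterministic given (spec, resolution, seed)", {
  a <- buildScene(sceneSpec("control"), seed = 5)
  b <- buildScene(sceneSpec("control"), seed = 5)
  expect_identical(a@meshes$presynaptic@vertices,
                   b@meshes$presynaptic@vertices)
  expect_identical(a@populations$GLT_1@positions,
                   b@populations$GLT_1@positions)
})

test_that("occupied volume fraction sums compartments over the world", {
  empty <- buildScene(sceneSpec("control", nAstro = 0, preVolume = 0,
                                postVolume = 0, transporterDensity = 0))
  expect_equal(occupiedVolumeFraction(empty), 0)

  ## tabulated compartment volumes: 0.07 + 0.04 + 0.10 in a 1 um^3 world
  boxes <- list(
    world = boxMesh(c(0, 0, 0), c(1, 1, 1), role = "world", inward = TRUE),
    presynaptic = boxMesh(c(0, 0, -0.3), c(0.41, 0.41, 0.41632)),
    postsynaptic = boxMesh(c(0, 0, 0.3), c(0.35, 0.35, 0.32653)),
    astrocyte_1 = boxMesh(c(0.35, 0, 0), c(0.2, 0.5, 1)))
  vols <- vapply(boxes[-1L], meshVolume, 0)
  sc <- new("Scene", spec = sceneSpec("control"), meshes = boxes,
            populations = list(), cleft = list(), seed = 1L)
  expect_equal(occupiedVolumeFraction(sc), sum(vols), tolerance = 1e-9)
  expect_equal(signif(sum(vols), 2), 0.21)

  full <- new("Scene", spec = sceneSpec("control"),
              meshes = list(world = boxes$world,
                            presynaptic = boxMesh(c(0, 0, 0), c(1, 1, 1))),
              populations = list(), cleft = list(), seed = 1L)
  expect_equal(occupiedVolumeFraction(full), 1)
})

test_that("local uptake capacity follows the density-times-area product", {
  expect_equal(localUptakeCapacity(10800, 1.79), 19332)
  ## per-synapse totals: control 1.79 um^2 vs PAR1-activated 2.52 um^2
  ctl <- localUptakeCapacity(10800, 1.79)
  tfl <- localUptakeCapacity(10800, 2.52)
  expect_equal(uptakeCapacityRatio(ctl, tfl), 100 * (2.52 / 1.79 - 1))
  expect_equal(round(uptakeCapacityRatio(ctl, tfl)), 41)
  expect_equal(uptakeCapacityRatio(5, 5), 0)
  expect_error(uptakeCapacityRatio(0, 5), "zero")
})

test_that("scene specs validate and round-trip through YAML", {
  expect_error(sceneSpec("control", transporterDensity = -1), ">= 0")
  expect_error(sceneSpec("control", cleftHeight = 500, preRadius = 0.3),
               "cleft")
  f <- tempfile(fileext = ".yaml")
  spec <- sceneSpec("tfllr", astroArea = 0.6)
  writeSceneSpec(spec, f)
  back <- readSceneSpec(f)
  for (s in slotNames("SceneSpec"))
    expect_equal(slot(back, s), slot(spec, s))
  writeLines(c("worldEdge: 1", "bogusKey: 2"), f)
  expect_error(readSceneSpec(f), "bogusKey")
})

test_that("packaged scene spec files load and match the presets", {
  ctl <- readSceneSpec(system.file("extdata", "scene_control.yaml",
                                   package = "GluClear"))
  expect_equal(ctl@astroArea, 0.69)
  expect_equal(ctl@nAstro, 2)
  tfl <- readSceneSpec(system.file("extdata", "scene_tfllr.yaml",
                                   package = "GluClear"))
  expect_equal(tfl@astroDistance, 190)
  expect_equal(tfl@nAstro, 4)
})
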