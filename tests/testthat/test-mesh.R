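test_that("mesh area and volume match closed forms", {
  cube <- unitCube()
  expect_equal(meshArea(cube), 6)
  expect_equal(meshVolume(cube), 1)

  ico <- icosphereMesh(0.27, 4)
  expect_lt(abs(meshArea(ico) / (4 * pi * 0.27^2) - 1), 0.01)
  expect_lt(abs(meshVolume(ico) / (4 / 3 * pi * 0.27^3) - 1), 0.01)

  ts <- truncatedSphereMesh(0.27, 0.2, edge = 0.02)
  expect_identical(nrow(meshBoundaryEdges(ts)), 0L)
  ## analytic: full sphere minus the spherical cap above z = 0.2
  h <- 0.27 - 0.2
  vExact <- 4 / 3 * pi * 0.27^3 - pi * h^2 * (3 * 0.27 - h) / 3
  expect_lt(abs(meshVolume(ts) / vExact - 1), 0.01)
})

test_that("volume is additive and orientation-robust", {
  a <- boxMesh(c(0, 0, 0), c(1, 1, 1))
  b <- boxMesh(c(3, 0, 0), c(2, 1, 1))
  both <- triMesh(rbind(a@vertices, b@vertices),
                  rbind(a@faces, b@faces + nrow(a@vertices)))
  expect_equal(meshVolume(both), 3)
  inward <- triMesh(a@vertices, a@faces[, c(1, 3, 2)])
  expect_warning(v <- meshVolume(inward), "inward")
  expect_equal(v, 1)
})

test_that("non-watertight meshes are rejected with boundary edges", {
  cube <- unitCube()
  open <- triMesh(cube@vertices, cube@faces[-1L, ])
  expect_error(meshVolume(open), "boundary edge")
  expect_gt(nrow(meshBoundaryEdges(open)), 0)
})

test_that("degenerate triangles are rejected at construction", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))   # collinear
  expect_error(triMesh(v, rbind(c(1, 2, 3))), "degenerate")
})

test_that("OBJ interchange round-trips bit-identically", {
  f <- tempfile(fileext = ".obj")
  cube <- unitCube()
  writeMeshOBJ(cube, f)
  back <- readMeshOBJ(f)
  expect_identical(back@vertices, unname(cube@vertices))
  expect_identical(back@faces, unname(cube@faces))
  expect_identical(back@role, "cube")
  expect_identical(nrow(back@vertices), 8L)
  expect_identical(nrow(back@faces), 12L)
  ## a second round trip of an irregular mesh
  ts <- truncatedSphereMesh(0.27, 0.203, edge = 0.05)
  writeMeshOBJ(ts, f)
  expect_identical(readMeshOBJ(f)@vertices, unname(ts@vertices))
})

test_that("OBJ reader rejects quads and missing files", {
  f <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), f)
  expect_error(readMeshOBJ(f), "face index 1")
  expect_error(readMeshOBJ(tempfile()), "not found")
})

test_that("nearest surface distance handles planes, spheres and touching", {
  sq <- function(z) triMesh(rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z),
                                  c(0, 1, z)),
                            rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(nearestSurfaceDistance(sq(0), sq(0.1)), 100)   # nm
  expect_equal(nearestSurfaceDistance(sq(0.1), sq(0)), 100)   # symmetric
  expect_equal(nearestSurfaceDistance(sq(0), sq(0)), 0)

  s1 <- icosphereMesh(0.2, 3, center = c(0, 0, 0))
  s2 <- icosphereMesh(0.3, 3, center = c(1, 0, 0))
  ## centers 1 um apart: surface gap 0.5 um; inscribed facets sit slightly
  ## inside the spheres so the mesh distance is marginally larger
  d <- nearestSurfaceDistance(s1, s2)
  expect_gt(d, 499)
  expect_lt(d, 505)
})

test_that("surface molecule placement is exact, uniform and seeded", {
  slab <- slabMesh(0.3, 0.05, 0.5818181818, 0.5)
  expect_equal(meshArea(slab), 0.69, tolerance = 1e-9)
  pop <- placeSurfaceMolecules(slab, 10800, seed = 7)
  expect_identical(nrow(pop@positions), 7452L)   # round(10800 * 0.69)
  expect_identical(length(pop@triangle), 7452L)

  expect_identical(placeSurfaceMolecules(slab, 0, seed = 1)@triangle,
                   integer(0))
  p2 <- placeSurfaceMolecules(slab, 10800, seed = 7)
  expect_identical(pop@positions, p2@positions)   # deterministic
  p3 <- placeSurfaceMolecules(slab, 10800, seed = 8)
  expect_false(identical(pop@positions, p3@positions))

  ## positions lie on the host triangles (barycentric reconstruction)
  a <- slab@vertices[slab@faces[pop@triangle, 1L], ]
  b <- slab@vertices[slab@faces[pop@triangle, 2L], ]
  c3 <- slab@vertices[slab@faces[pop@triangle, 3L], ]
  rec <- a * pop@bary[, 1L] + b * pop@bary[, 2L] + c3 * pop@bary[, 3L]
  expect_lt(max(abs(rec - pop@positions)), 1e-12)

  ## chi-square uniformity of triangle occupancy on a sphere
  sph <- icosphereMesh(0.5, 2)
  n <- 1e5
  pop <- placeSurfaceMolecules(sph, n / meshArea(sph), seed = 3)
  areas <- triangleAreas(sph@vertices, sph@faces)
  obs <- tabulate(pop@triangle, nbins = nrow(sph@faces))
  expected <- length(pop@triangle) * areas / sum(areas)
  chi2 <- sum((obs - expected)^2 / expected)
  pval <- pchisq(chi2, df = nrow(sph@faces) - 1L, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})
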