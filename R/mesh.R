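## Triangle mesh primitives: construction, measurement, OBJ interchange and
## uniform surface sampling. All coordinates are in micrometres.

triangleAreas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangleNormals <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n / sqrt(rowSums(n^2))
}

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix n x 3 (um).
#' @param faces matrix m x 3 of 1-based vertex indices.
#' @param role compartment label.
#' @return A \code{\linkS4class{TriMesh}}.
#' @export
triMesh <- function(vertices, faces, role = "unlabelled") {
  storage.mode(faces) <- "integer"
  new("TriMesh", vertices = as.matrix(vertices), faces = faces, role = role)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas; additive over disjoint submeshes.
#'
#' @param mesh a \code{TriMesh}.
#' @return Area in um^2.
#' @export
meshArea <- function(mesh) {
  if (nrow(mesh@faces) == 0L) stop("mesh has no faces")
  sum(triangleAreas(mesh@vertices, mesh@faces))
}

#' Boundary edges of a mesh
#'
#' Edges not shared by exactly two faces (with opposite winding). Empty for a
#' watertight, consistently oriented mesh.
#'
#' @param mesh a \code{TriMesh}.
#' @return Integer matrix of offending (directed) edges, possibly 0-row.
#' @export
meshBoundaryEdges <- function(mesh) {
  f <- mesh@faces
  ed <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(ed[, 1L], ed[, 2L])
  rkey <- paste(ed[, 2L], ed[, 1L])
  bad <- !(rkey %in% key) | duplicated(key) | duplicated(key, fromLast = TRUE)
  ed[bad, , drop = FALSE]
}

#' Enclosed volume of a watertight mesh
#'
#' Signed divergence-theorem volume, returned positive. An inward-oriented
#' mesh yields the same magnitude with a warning.
#'
#' @param mesh a watertight, consistently oriented \code{TriMesh}.
#' @return Volume in um^3.
#' @export
meshVolume <- function(mesh) {
  be <- meshBoundaryEdges(mesh)
  if (nrow(be) > 0L)
    stop("mesh is not watertight; ", nrow(be), " boundary edge(s), first: ",
         paste(be[1L, ], collapse = "-"))
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  vol <- sum(a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
             a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
             a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
  if (vol < 0) {
    warning("mesh is inward-oriented; returning |volume|")
    vol <- -vol
  }
  vol
}

## ---------------------------------------------------------------------------
## Parametric meshes
## ---------------------------------------------------------------------------

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere.
#'
#' @param radius sphere radius (um).
#' @param subdivisions number of 4-to-1 subdivision rounds.
#' @param center length-3 center.
#' @param role compartment label.
#' @return A watertight \code{TriMesh}.
#' @export
icosphereMesh <- function(radius, subdivisions = 3L, center = c(0, 0, 0),
                          role = "unlabelled") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    nv <- nrow(v)
    edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1L, sort)))
    mid <- (v[edges[, 1L], ] + v[edges[, 2L], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    key <- paste(edges[, 1L], edges[, 2L])
    midIdx <- function(i1, i2) {
      k <- paste(pmin(i1, i2), pmax(i1, i2))
      nv + match(k, key)
    }
    m12 <- midIdx(f[, 1L], f[, 2L])
    m23 <- midIdx(f[, 2L], f[, 3L])
    m31 <- midIdx(f[, 3L], f[, 1L])
    v <- rbind(v, mid)
    f <- rbind(cbind(f[, 1L], m12, m31), cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m31, m23), cbind(m12, m23, m31))
  }
  triMesh(sweep(v * radius, 2L, center, "+"), f, role)
}

## Stitch two concentric vertex rings (equal counts, or differing by a
## factor of two) into a consistently wound triangle band. `inIdx` is the
## ring nearer the local center/pole of the ring chain.
ringStitch <- function(inIdx, outIdx) {
  nI <- length(inIdx); nO <- length(outIdx)
  if (nO == nI) {
    j <- seq_len(nI); jp <- j %% nI + 1L
    rbind(cbind(inIdx[j], outIdx[j], outIdx[jp]),
          cbind(inIdx[j], outIdx[jp], inIdx[jp]))
  } else if (nO == 2L * nI) {
    j <- seq_len(nI); jp <- j %% nI + 1L
    o1 <- 2L * j - 1L; o2 <- 2L * j; o3 <- (2L * j) %% nO + 1L
    rbind(cbind(inIdx[j], outIdx[o1], outIdx[o2]),
          cbind(inIdx[j], outIdx[o2], inIdx[jp]),
          cbind(inIdx[jp], outIdx[o2], outIdx[o3]))
  } else if (nI == 2L * nO) {
    ringStitch(outIdx, inIdx)[, c(1L, 3L, 2L), drop = FALSE]
  } else stop("ring counts must be equal or differ by a factor of 2")
}

## point count per ring: start at 8, double/halve as the circumference grows
## or shrinks relative to the target edge length
ringCounts <- function(circumferences, edge, first = 8L) {
  n <- integer(length(circumferences))
  n[1L] <- max(first, 8L)
  for (k in seq_along(n)[-1L]) {
    prev <- n[k - 1L]
    arc <- circumferences[k] / prev
    n[k] <- if (arc > 1.4 * edge) 2L * prev
            else if (arc < 0.6 * edge && prev > 8L) prev %/% 2L
            else prev
  }
  n
}

## Closed surface from a chain of rings capped with a vertex at each end.
## `ringXYZ(k, phi)` returns the ring-k vertex positions for angles `phi`.
ringChainMesh <- function(nRings, counts, ringXYZ, startPoint, endPoint,
                          role) {
  v <- rbind(startPoint)
  ringIdx <- vector("list", nRings)
  for (k in seq_len(nRings)) {
    phi <- 2 * pi * (seq_len(counts[k]) - 1L) / counts[k]
    ringIdx[[k]] <- nrow(v) + seq_along(phi)
    v <- rbind(v, ringXYZ(k, phi))
  }
  endIdx <- nrow(v) + 1L
  v <- rbind(v, endPoint)
  j1 <- seq_len(counts[1L])
  f <- cbind(1L, ringIdx[[1L]][j1], ringIdx[[1L]][j1 %% counts[1L] + 1L])
  for (k in seq_len(nRings)[-1L])
    f <- rbind(f, ringStitch(ringIdx[[k - 1L]], ringIdx[[k]]))
  jn <- seq_len(counts[nRings])
  f <- rbind(f, cbind(endIdx, ringIdx[[nRings]][jn %% counts[nRings] + 1L],
                      ringIdx[[nRings]][jn]))
  m <- triMesh(v, f, role)
  orientOutward(m)
}

## flip faces if the signed volume is negative (watertight meshes only)
orientOutward <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  vol <- sum(a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
             a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
             a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
  if (vol < 0) mesh@faces <- mesh@faces[, c(1L, 3L, 2L)]
  mesh
}

#' Truncated-sphere mesh
#'
#' Sphere of given radius centred at the origin, cut by the plane
#' \code{z = cut}; the part with \code{z <= cut} is kept and closed with a
#' flat disc (the apposition face). \code{cut = 0} gives a hemisphere.
#' Built as a chain of latitude rings from the bottom pole to the cut
#' circle, continued by concentric cap rings, with ring point counts
#' adapting to the target edge length (so triangle sizes stay roughly
#' uniform and no vertex accumulates a large fan).
#'
#' @param radius sphere radius (um).
#' @param cut height of the truncation plane above the center (um),
#'   in (-radius, radius).
#' @param edge target edge length (um).
#' @param role compartment label.
#' @return A watertight, outward-oriented \code{TriMesh} with its flat face
#'   at \code{z = cut}.
#' @export
truncatedSphereMesh <- function(radius, cut, edge = 0.02, role = "unlabelled") {
  stopifnot(cut > -radius, cut < radius)
  theta0 <- acos(cut / radius)          # polar angle of the cut circle
  nT <- max(3L, ceiling(radius * (pi - theta0) / edge))
  thetas <- seq(pi, theta0, length.out = nT + 1L)[-1L]   # pole excluded
  rc <- radius * sin(theta0)
  nC <- max(2L, ceiling(rc / edge))
  capR <- rc * (nC - seq_len(nC - 1L)) / nC              # outer -> inner
  circ <- c(2 * pi * radius * sin(thetas), 2 * pi * capR)
  counts <- ringCounts(circ, edge)
  nRings <- length(circ)
  ringXYZ <- function(k, phi) {
    if (k <= nT) {
      th <- thetas[k]
      cbind(radius * sin(th) * cos(phi), radius * sin(th) * sin(phi),
            radius * cos(th))
    } else {
      r <- capR[k - nT]
      cbind(r * cos(phi), r * sin(phi), cut)
    }
  }
  ringChainMesh(nRings, counts, ringXYZ, startPoint = c(0, 0, -radius),
                endPoint = c(0, 0, cut), role = role)
}

#' Axis-aligned box mesh
#'
#' @param center length-3 box center (um).
#' @param dims length-3 edge lengths (um).
#' @param role compartment label.
#' @param inward if TRUE, orient faces inward (a sealed world box whose
#'   interior is the simulation domain).
#' @return A watertight \code{TriMesh} of 12 triangles.
#' @export
boxMesh <- function(center, dims, role = "unlabelled", inward = FALSE) {
  h <- dims / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8L), 2L, center, "+")
  ## vertex order: (-,-,-)(+,-,-)(-,+,-)(+,+,-)(-,-,+)(+,-,+)(-,+,+)(+,+,+)
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # z-
             c(5, 6, 7), c(6, 8, 7),    # z+
             c(1, 2, 5), c(2, 6, 5),    # y-
             c(3, 7, 4), c(4, 7, 8),    # y+
             c(1, 5, 3), c(3, 5, 7),    # x-
             c(2, 4, 6), c(4, 8, 6))    # x+
  if (inward) f <- f[, c(1L, 3L, 2L)]
  triMesh(v, f, role)
}

#' Flat disc mesh (surface only)
#'
#' Concentric-ring triangulation of a disc in the plane \code{z = z0}; used
#' for the PSD. Not watertight (it encloses no volume).
#'
#' @param radius disc radius (um).
#' @param z0 plane height (um).
#' @param edge target triangle edge length (um).
#' @param role compartment label.
#' @param facing +1 for normal along +z, -1 for -z.
#' @return A \code{TriMesh}.
#' @export
discMesh <- function(radius, z0 = 0, edge = radius / 8, role = "PSD",
                     facing = 1) {
  nR <- max(2L, ceiling(radius / edge))
  radii <- radius * seq_len(nR) / nR
  counts <- ringCounts(2 * pi * radii, edge)
  v <- matrix(c(0, 0, z0), 1L)
  ringIdx <- vector("list", nR)
  for (k in seq_len(nR)) {
    phi <- 2 * pi * (seq_len(counts[k]) - 1L) / counts[k]
    ringIdx[[k]] <- nrow(v) + seq_along(phi)
    v <- rbind(v, cbind(radii[k] * cos(phi), radii[k] * sin(phi), z0))
  }
  j1 <- seq_len(counts[1L])
  f <- cbind(1L, ringIdx[[1L]][j1], ringIdx[[1L]][j1 %% counts[1L] + 1L])
  for (k in seq_len(nR)[-1L])
    f <- rbind(f, ringStitch(ringIdx[[k - 1L]], ringIdx[[k]]))
  if (facing < 0) f <- f[, c(1L, 3L, 2L)]
  triMesh(v, f, role)
}

#' Thin rectangular slab mesh
#'
#' Box of thickness \code{thick} whose inner face is the plane normal to
#' \code{+x} at \code{x = x0}, spanning \code{width} in y and \code{height}
#' in z, centred on \code{(yc, zc)}; used for astrocytic sheets before
#' rotation into place.
#' @keywords internal
slabMesh <- function(x0, thick, width, height, yc = 0, zc = 0,
                     role = "astrocyte") {
  boxMesh(center = c(x0 + thick / 2, yc, zc),
          dims = c(thick, width, height), role = role)
}

#' Curved sheet mesh (cylindrical segment)
#'
#' A thin curved slab: the solid between two coaxial cylinder surfaces of
#' radii \code{rho} and \code{rho + thick}, spanning \code{phiWidth}
#' radians (centred on azimuth 0) and \code{height} along z (centred on
#' z = 0). The shape used for astrocytic sheets wrapped around the cleft
#' axis.
#'
#' @param rho inner surface radius (um).
#' @param thick radial thickness (um).
#' @param phiWidth angular width (radians).
#' @param height extent along z (um).
#' @param edge target edge length for the angular subdivision (um).
#' @param role compartment label.
#' @return A watertight, outward-oriented \code{TriMesh}.
#' @export
curvedSheetMesh <- function(rho, thick, phiWidth, height, edge = 0.02,
                            role = "astrocyte") {
  stopifnot(rho > 0, thick > 0, phiWidth > 0, phiWidth < 2 * pi,
            height > 0)
  n <- max(4L, ceiling(phiWidth * (rho + thick) / edge))
  phis <- seq(-phiWidth / 2, phiWidth / 2, length.out = n + 1L)
  zlo <- -height / 2; zhi <- height / 2
  rin <- rho; rout <- rho + thick
  ## vertex layout: for each angle i, corners (rin,zlo) (rin,zhi)
  ## (rout,zlo) (rout,zhi)
  v <- do.call(rbind, lapply(phis, function(p)
    rbind(c(rin * cos(p), rin * sin(p), zlo),
          c(rin * cos(p), rin * sin(p), zhi),
          c(rout * cos(p), rout * sin(p), zlo),
          c(rout * cos(p), rout * sin(p), zhi))))
  id <- function(i, corner) (i - 1L) * 4L + corner  # corner in 1:4
  f <- NULL
  quad <- function(a, b, c3, d) rbind(c(a, b, c3), c(a, c3, d))
  for (i in seq_len(n)) {
    f <- rbind(f,
      quad(id(i, 3), id(i + 1, 3), id(i + 1, 4), id(i, 4)),   # outer, +r
      quad(id(i, 1), id(i, 2), id(i + 1, 2), id(i + 1, 1)),   # inner, -r
      quad(id(i, 2), id(i, 4), id(i + 1, 4), id(i + 1, 2)),   # top, +z
      quad(id(i, 1), id(i + 1, 1), id(i + 1, 3), id(i, 3)))   # bottom, -z
  }
  f <- rbind(f,
    quad(id(1, 1), id(1, 3), id(1, 4), id(1, 2)),             # end -phi
    quad(id(n + 1, 1), id(n + 1, 2), id(n + 1, 4), id(n + 1, 3)))
  orientOutward(triMesh(v, f, role))
}

rotateZ <- function(mesh, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3L, 3L)
  mesh@vertices <- mesh@vertices %*% R
  mesh
}

## ---------------------------------------------------------------------------
## Wavefront OBJ interchange
## ---------------------------------------------------------------------------

#' Read a triangle mesh from a Wavefront OBJ file
#'
#' Only \code{v} and \code{f} records are interpreted; faces must be
#' triangles. The first \code{o}/\code{g} name, if any, becomes the role.
#'
#' @param path OBJ file path.
#' @return A \code{TriMesh}.
#' @export
readMeshOBJ <- function(path) {
  if (!file.exists(path)) stop("OBJ file not found: ", path)
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  tags <- vapply(toks, function(x) if (length(x)) x[1L] else "", "")
  v <- do.call(rbind, lapply(toks[tags == "v"], function(x)
    as.numeric(x[2:4])))
  fr <- toks[tags == "f"]
  role <- "unlabelled"
  named <- toks[tags %in% c("o", "g")]
  if (length(named)) role <- named[[1L]][2L]
  f <- lapply(seq_along(fr), function(i) {
    x <- fr[[i]][-1L]
    if (length(x) != 3L)
      stop("non-triangular face at face index ", i, " (", length(x),
           " vertices)")
    as.integer(vapply(strsplit(x, "/"), `[`, "", 1L))
  })
  triMesh(v, do.call(rbind, f), role)
}

#' Write a triangle mesh to a Wavefront OBJ file
#'
#' Coordinates are written with full double precision so that
#' \code{readMeshOBJ(writeMeshOBJ(m))} round-trips bit-identically.
#'
#' @param mesh a \code{TriMesh}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMeshOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("o", mesh@role), con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh@vertices[, 1L],
                     mesh@vertices[, 2L], mesh@vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh@faces[, 1L], mesh@faces[, 2L],
                     mesh@faces[, 3L]), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Distances
## ---------------------------------------------------------------------------

pointTriangleDist2 <- function(p, a, b, c3) {
  ## squared distance from point p to triangle (a,b,c3); Ericson's method
  ab <- b - a; ac <- c3 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sum((p - a)^2))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sum((p - b)^2))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sum((p - (a + t * ab))^2))
  }
  cp <- p - c3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sum((p - c3)^2))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sum((p - (a + t * ac))^2))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sum((p - (b + t * (c3 - b)))^2))
  }
  denom <- 1 / (va + vb + vc)
  q <- a + ab * (vb * denom) + ac * (vc * denom)
  sum((p - q)^2)
}

segSegDist2 <- function(p1, q1, p2, q2) {
  ## squared distance between segments p1-q1 and p2-q2
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-300
  if (a <= eps && e <= eps) return(sum(r * r))
  if (a <= eps) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c0 <- sum(d1 * r)
    if (e <= eps) { t <- 0; s <- min(max(-c0 / a, 0), 1) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > eps) min(max((b * f - c0 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c0 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c0) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sum(v * v)
}

triTriDist <- function(va, fa, vb, fb) {
  A <- list(va[fa[1L], ], va[fa[2L], ], va[fa[3L], ])
  B <- list(vb[fb[1L], ], vb[fb[2L], ], vb[fb[3L], ])
  best <- Inf
  for (p in A) best <- min(best, pointTriangleDist2(p, B[[1L]], B[[2L]], B[[3L]]))
  for (p in B) best <- min(best, pointTriangleDist2(p, A[[1L]], A[[2L]], A[[3L]]))
  eA <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (ea in eA) for (eb in eA)
    best <- min(best, segSegDist2(A[[ea[1L]]], A[[ea[2L]]],
                                  B[[eb[1L]]], B[[eb[2L]]]))
  sqrt(best)
}

#' Nearest distance between two mesh surfaces
#'
#' Minimum Euclidean distance between the triangle sets (face-to-face, with
#' point-triangle and edge-edge cases handled exactly). Symmetric; 0 when the
#' surfaces touch.
#'
#' @param a,b \code{TriMesh} objects.
#' @return Distance in nm.
#' @export
nearestSurfaceDistance <- function(a, b) {
  if (nrow(a@faces) == 0L || nrow(b@faces) == 0L)
    stop("both meshes must be non-empty")
  va <- a@vertices; fa <- a@faces
  vb <- b@vertices; fb <- b@faces
  cenA <- (va[fa[, 1L], , drop = FALSE] + va[fa[, 2L], , drop = FALSE] +
           va[fa[, 3L], , drop = FALSE]) / 3
  cenB <- (vb[fb[, 1L], , drop = FALSE] + vb[fb[, 2L], , drop = FALSE] +
           vb[fb[, 3L], , drop = FALSE]) / 3
  radTri <- function(v, f, cen) {
    d2 <- pmax(rowSums((v[f[, 1L], , drop = FALSE] - cen)^2),
               rowSums((v[f[, 2L], , drop = FALSE] - cen)^2),
               rowSums((v[f[, 3L], , drop = FALSE] - cen)^2))
    sqrt(d2)
  }
  rA <- radTri(va, fa, cenA); rB <- radTri(vb, fb, cenB)
  ## lower bound per pair: centroid distance minus both circumradii
  dc <- sqrt(outer(rowSums(cenA^2), rowSums(cenB^2), "+") -
               2 * cenA %*% t(cenB))
  lb <- dc - outer(rA, rB, "+")
  ord <- order(lb)
  best <- Inf
  for (k in ord) {
    i <- (k - 1L) %% nrow(lb) + 1L
    j <- (k - 1L) %/% nrow(lb) + 1L
    if (lb[k] >= best) break
    best <- min(best, triTriDist(va, fa[i, ], vb, fb[j, ]))
    if (best <= 0) break
  }
  best * 1e3   # um -> nm
}

## ---------------------------------------------------------------------------
## Surface sampling
## ---------------------------------------------------------------------------

#' Place surface molecules uniformly on a mesh
#'
#' Deterministic count \code{round(density * meshArea(mesh))}; positions are
#' uniform over the surface (area-weighted triangle choice, uniform
#' barycentric sampling). Reproducible for a fixed seed.
#'
#' @param mesh host \code{TriMesh}.
#' @param density surface density (um^-2).
#' @param species species label.
#' @param seed integer RNG seed.
#' @return A \code{\linkS4class{SurfacePopulation}}.
#' @export
placeSurfaceMolecules <- function(mesh, density, species = "GLT", seed = 1L) {
  stopifnot(density >= 0)
  areas <- triangleAreas(mesh@vertices, mesh@faces)
  total <- sum(areas)
  n <- round(density * total)
  if (n == 0L) {
    return(new("SurfacePopulation", species = species, hostRole = mesh@role,
               triangle = integer(0), bary = matrix(numeric(0), 0, 3),
               positions = matrix(numeric(0), 0, 3),
               tileArea = if (density > 0) 1 / density else 0))
  }
  rs <- localRNG(seed)
  tri <- sample.int(length(areas), n, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  localRNGRestore(rs)
  u <- 1 - r1; v <- r1 * (1 - r2); w <- r1 * r2
  bary <- cbind(u, v, w)
  a <- mesh@vertices[mesh@faces[tri, 1L], , drop = FALSE]
  b <- mesh@vertices[mesh@faces[tri, 2L], , drop = FALSE]
  c3 <- mesh@vertices[mesh@faces[tri, 3L], , drop = FALSE]
  pos <- a * u + b * v + c3 * w
  new("SurfacePopulation", species = species, hostRole = mesh@role,
      triangle = as.integer(tri), bary = bary, positions = pos,
      tileArea = total / n)
}

## seed scoping helpers: set a local RNG state and restore the caller's
localRNG <- function(seed) {
  prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  prev
}
localRNGRestore <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", prev, envir = globalenv())
  invisible(NULL)
}

#' @describeIn TriMesh-class compact display
#' @param object a \code{TriMesh}
#' @export
setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh '%s': %d vertices, %d faces, area %.4g um^2\n",
              object@role, nrow(object@vertices), nrow(object@faces),
              if (nrow(object@faces)) meshArea(object) else 0))
})
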