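## Simplified synapse scenes: a 1 um^3 world holding two apposed terminals
## separated by a 20 nm cleft, a PSD disc on the postsynaptic cleft face, and
## thin astrocytic sheets arranged symmetrically around the cleft axis.
## Convention: synapse axis = +z from pre to post, world centred on the cleft
## center, all lengths in um unless a slot says nm.

#' Create a scene specification
#'
#' Returns a \code{\linkS4class{SceneSpec}} for one of the named presets, with
#' optional field overrides. \code{"control"} and \code{"tfllr"} follow the
#' narrative description of the simplified simulations (2 processes of
#' 0.69 um^2 at 116 nm vs 4 of 0.54 um^2 at 190 nm); the \code{"_table2"}
#' variants use the tabulated per-process areas instead (0.89 and 0.60 um^2).
#'
#' @param condition preset name.
#' @param ... named \code{SceneSpec} slots to override.
#' @return A \code{SceneSpec}.
#' @export
sceneSpec <- function(condition = c("control", "tfllr", "control_table2",
                                    "tfllr_table2"), ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    control = list(),
    tfllr = list(preVolume = 0.065, preRadius = 0.24, postVolume = 0.029,
                 postRadius = 0.24, nAstro = 4, astroArea = 0.54,
                 astroDistance = 190),
    control_table2 = list(preVolume = 0.07, postVolume = 0.04,
                          astroArea = 0.89),
    tfllr_table2 = list(preVolume = 0.06, preRadius = 0.24, postVolume = 0.03,
                        postRadius = 0.24, nAstro = 4, astroArea = 0.60,
                        astroDistance = 190))
  args <- modifyList(base, list(...))
  do.call(new, c(list("SceneSpec"), args))
}

#' Read / write a scene specification as YAML
#'
#' Keys mirror the \code{SceneSpec} slot names.
#'
#' @param path YAML file path.
#' @return \code{readSceneSpec}: a \code{SceneSpec}.
#' @export
readSceneSpec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- slotNames("SceneSpec")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown scene spec key(s): ", paste(bad, collapse = ", "))
  do.call(new, c(list("SceneSpec"), vals))
}

#' @rdname readSceneSpec
#' @param spec a \code{SceneSpec}.
#' @export
writeSceneSpec <- function(spec, path) {
  vals <- lapply(slotNames("SceneSpec"), function(s) slot(spec, s))
  names(vals) <- slotNames("SceneSpec")
  yaml::write_yaml(vals, path)
  invisible(path)
}

## Astrocytic sheet dimensions realising a per-process area as a curved
## (cylindrical-segment) sheet of thickness `thick`: prefer a fixed height,
## and when the required angular width would make neighbouring sheets
## touch, grow the sheet vertically instead. Total area of the segment is
## phi (2 rho + thick)(H + thick) + 2 thick H.
astroSheetDims <- function(area, rho, nA, worldEdge, thick = 0.05) {
  if (rho + thick > 0.49 * worldEdge)
    stop("geometry infeasible: processes at this distance do not fit ",
         "inside the world box")
  phiMax <- 0.95 * 2 * pi / max(nA, 1L)
  H <- min(0.5, 0.8 * worldEdge)
  phi <- (area - 2 * thick * H) / ((2 * rho + thick) * (H + thick))
  if (phi <= 0)
    stop("geometry infeasible: per-process area too small for a ",
         thick * 1e3, " nm sheet")
  if (phi > phiMax) {
    phi <- phiMax
    H <- (area - phi * (2 * rho + thick) * thick) /
      (phi * (2 * rho + thick) + 2 * thick)
    if (H > 0.96 * worldEdge)
      stop("geometry infeasible: per-process area too large for the ",
           "available space around the cleft axis")
  }
  list(phi = phi, H = H)
}

## mirror a mesh through the plane z = 0, preserving outward orientation
mirrorZ <- function(mesh) {
  mesh@vertices[, 3L] <- -mesh@vertices[, 3L]
  mesh@faces <- mesh@faces[, c(1L, 3L, 2L)]
  mesh
}

terminalMesh <- function(radius, volume, appositionRadius, faceZ, side,
                         edge, role) {
  ## truncated sphere whose flat face (radius = appositionRadius) meets the
  ## cleft; uniformly scaled to the requested volume, then translated so the
  ## flat face sits at z = faceZ. side = -1 (pre, below cleft) or +1 (post).
  if (appositionRadius >= radius)
    stop("geometry infeasible: apposition radius exceeds terminal radius")
  cut <- sqrt(radius^2 - appositionRadius^2)
  m <- truncatedSphereMesh(radius, cut, edge = edge, role = role)
  s <- (volume / meshVolume(m))^(1 / 3)
  m@vertices <- m@vertices * s
  if (side > 0) m <- mirrorZ(m)
  ## flat face currently at z = -side * cut * s; move it to faceZ
  m@vertices[, 3L] <- m@vertices[, 3L] + side * cut * s + faceZ
  m
}

#' Build a simplified synapse scene
#'
#' Constructs the compartment meshes from a \code{SceneSpec}: spherical
#' terminals truncated at the cleft and uniformly rescaled to the stated
#' volumes, a PSD disc on the postsynaptic cleft face, and \code{nAstro}
#' thin (50 nm) rectangular astrocytic sheets placed symmetrically around
#' the cleft axis with their inner face at the stated nearest distance from
#' the PSD; each sheet is dimensioned so its total mesh area equals the
#' per-process area. Glutamate transporters are placed on the astrocytic
#' sheets at the stated density; GluA/GluN populations are placed on the PSD
#' and (extrasynaptically) on the postsynaptic membrane when
#' \code{receptors = TRUE}.
#'
#' @param spec a \code{\linkS4class{SceneSpec}}.
#' @param edge target mesh edge length (um, default 0.02).
#' @param seed integer seed for molecule placement.
#' @param receptors place receptor populations as well as transporters.
#' @return A \code{\linkS4class{Scene}}.
#' @export
buildScene <- function(spec, edge = 0.02, seed = 1L, receptors = FALSE) {
  validObject(spec)
  h <- spec@cleftHeight * 1e-3         # nm -> um
  half <- spec@worldEdge / 2
  a <- sqrt(spec@psdArea / pi)         # PSD / apposition radius
  meshes <- list()
  meshes$world <- boxMesh(c(0, 0, 0), rep(spec@worldEdge, 3L), role = "world",
                          inward = TRUE)
  if (spec@preVolume > 0)
    meshes$presynaptic <- terminalMesh(spec@preRadius, spec@preVolume, a,
                                       faceZ = -h / 2, side = -1, edge = edge,
                                       role = "presynaptic")
  if (spec@postVolume > 0)
    meshes$postsynaptic <- terminalMesh(spec@postRadius, spec@postVolume, a,
                                        faceZ = +h / 2, side = +1, edge = edge,
                                        role = "postsynaptic")
  ## PSD disc sits 0.5 nm inside the cleft (off the coplanar postsynaptic
  ## face), with its normal facing the cleft
  meshes$PSD <- discMesh(a, z0 = h / 2 - 5e-4, role = "PSD",
                         edge = edge, facing = -1)

  nA <- as.integer(spec@nAstro)
  if (nA > 0L) {
    t0 <- 0.05                          # sheet thickness (um)
    rho <- a + spec@astroDistance * 1e-3   # inner-face radius
    dims <- astroSheetDims(spec@astroArea, rho, nA, spec@worldEdge, t0)
    for (k in seq_len(nA)) {
      ang <- 2 * pi * (k - 1) / nA
      m <- curvedSheetMesh(rho, t0, dims$phi, dims$H, edge = edge,
                           role = "astrocyte")
      m <- rotateZ(m, ang)
      if (any(abs(m@vertices) > half + 1e-12))
        stop("geometry infeasible: astrocytic process ", k,
             " does not fit inside the world box at the stated distance")
      meshes[[paste0("astrocyte_", k)]] <- m
    }
    ## processes must clear the terminals
    solidRoles <- intersect(c("presynaptic", "postsynaptic"), names(meshes))
    for (r in solidRoles) {
      rmax <- max(sqrt(rowSums(meshes[[r]]@vertices[, 1:2, drop = FALSE]^2)))
      if (rmax >= rho)
        stop("geometry infeasible: astrocytic sheets at ", spec@astroDistance,
             " nm intersect the ", r, " terminal")
    }
  }

  pops <- list()
  if (nA > 0L && spec@transporterDensity > 0) {
    for (k in seq_len(nA)) {
      nm <- paste0("astrocyte_", k)
      pops[[paste0("GLT_", k)]] <- placeSurfaceMolecules(
        meshes[[nm]], spec@transporterDensity, species = "GLT",
        seed = seed + k)
      pops[[paste0("GLT_", k)]]@hostRole <- nm
    }
  }
  if (receptors) {
    recs <- list(
      list("GluA_PSD", "PSD", spec@gluaPsdDensity, "GluA"),
      list("GluN_PSD", "PSD", spec@glunPsdDensity, "GluN"),
      list("GluA_extra", "postsynaptic", spec@gluaExtraDensity, "GluA"),
      list("GluN_extra", "postsynaptic", spec@glunExtraDensity, "GluN"))
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      if (!r[[2]] %in% names(meshes) || r[[3]] <= 0) next
      p <- placeSurfaceMolecules(meshes[[r[[2]]]], r[[3]], species = r[[4]],
                                 seed = seed + 100L + i)
      p@hostRole <- r[[2]]
      pops[[r[[1]]]] <- p
    }
  }
  new("Scene", spec = spec, meshes = meshes, populations = pops,
      cleft = list(radius = a, zmin = -h / 2, zmax = h / 2),
      seed = as.integer(seed))
}

#' Fraction of the world volume occupied by solid compartments
#'
#' Sum of watertight compartment volumes (terminals and astrocytic sheets;
#' the PSD is a surface and the world box is the domain) over the world
#' volume.
#'
#' @param scene a \code{Scene}.
#' @return Fraction in [0, 1].
#' @export
occupiedVolumeFraction <- function(scene) {
  solid <- setdiff(names(scene@meshes), c("world", "PSD"))
  tot <- sum(vapply(solid, function(nm) meshVolume(scene@meshes[[nm]]), 0))
  tot / scene@spec@worldEdge^3
}

#' Local glutamate uptake capacity
#'
#' Transporter count available near one synapse: surface density times total
#' astrocytic surface area.
#'
#' @param density transporter surface density (um^-2).
#' @param totalAstroArea summed astrocytic surface area (um^2).
#' @return Transporter count.
#' @export
localUptakeCapacity <- function(density, totalAstroArea) {
  stopifnot(density >= 0, totalAstroArea >= 0)
  density * totalAstroArea
}

#' Percent change in uptake capacity between two conditions
#'
#' @param capacityA reference capacity (e.g. control).
#' @param capacityB comparison capacity (e.g. after PAR1 activation).
#' @return Percent change, \code{100 * (capacityB/capacityA - 1)}.
#' @export
uptakeCapacityRatio <- function(capacityA, capacityB) {
  if (capacityA == 0) stop("reference capacity is zero; ratio undefined")
  100 * (capacityB / capacityA - 1)
}

#' Summed astrocytic mesh area of a scene
#'
#' @param scene a \code{Scene}.
#' @return Total astrocytic surface area (um^2).
#' @export
sceneAstroArea <- function(scene) {
  nms <- grep("^astrocyte_", names(scene@meshes), value = TRUE)
  if (!length(nms)) return(0)
  sum(vapply(nms, function(nm) meshArea(scene@meshes[[nm]]), 0))
}

#' @describeIn Scene-class compact display
#' @param object a \code{Scene}
#' @export
setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d compartments, %d populations\n",
              length(object@meshes), length(object@populations)))
  for (nm in names(object@meshes)) {
    m <- object@meshes[[nm]]
    cat(sprintf("  %-14s %5d faces, area %.3f um^2\n", nm,
                nrow(m@faces), meshArea(m)))
  }
  for (nm in names(object@populations)) {
    p <- object@populations[[nm]]
    cat(sprintf("  pop %-10s %s on %s, n = %d\n", nm, p@species, p@hostRole,
                nrow(p@positions)))
  }
})

#' @describeIn SceneSpec-class compact display
#' @param object a \code{SceneSpec}
#' @export
setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:\n")
  for (s in slotNames("SceneSpec"))
    cat(sprintf("  %-18s %g\n", s, slot(object, s)))
})
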