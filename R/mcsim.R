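## R-side interface to the particle-based Monte Carlo reaction-diffusion
## engine: configuration, scene/scheme marshalling, seed averaging and
## engine calibration utilities.

AVOGADRO <- 6.02214076e23
CM2_TO_UM2 <- 1e8   # cm^2/s -> um^2/s

#' Create a Monte Carlo simulation configuration
#'
#' @param ... named \code{\linkS4class{SimConfig}} slots to override
#'   (e.g. \code{nIterations}, \code{nMolecules}, \code{dCleft}).
#' @return A \code{SimConfig}.
#' @export
simConfig <- function(...) {
  args <- list(...)
  do.call(new, c(list("SimConfig"), args))
}

## provenance hash over everything that determines a run
configHash <- function(scene, schemes, config) {
  key <- list(
    spec = lapply(slotNames("SceneSpec"), function(s) slot(scene@spec, s)),
    meshes = lapply(scene@meshes, function(m) c(nrow(m@vertices),
                                                nrow(m@faces))),
    pops = lapply(scene@populations, function(p)
      list(p@species, nrow(p@positions), p@tileArea)),
    placementSeed = scene@seed,
    schemes = lapply(schemes, function(s) s@transitions),
    config = lapply(setdiff(slotNames("SimConfig"), "nSeeds"),
                    function(s) slot(config, s)))
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(key, f)
  unname(tools::md5sum(f))
}

## convert a KineticScheme into the engine's per-state transition tables
schemeForEngine <- function(scheme) {
  states <- scheme@states
  n <- length(states)
  tr <- scheme@transitions
  uniTo <- vector("list", n); uniRate <- vector("list", n)
  uniEff <- vector("list", n)
  bindTo <- rep(-1L, n); konVol <- rep(0, n)
  effCode <- c(none = 0L, consume = 0L, release = 1L, sequester = 2L)
  for (i in seq_len(n)) {
    uniTo[[i]] <- integer(0); uniRate[[i]] <- numeric(0)
    uniEff[[i]] <- integer(0)
  }
  for (k in seq_len(nrow(tr))) {
    from <- match(tr$from[k], states) ; to <- match(tr$to[k], states)
    if (is.na(tr$ligand[k])) {
      uniTo[[from]] <- c(uniTo[[from]], to - 1L)
      uniRate[[from]] <- c(uniRate[[from]], tr$rate[k])
      uniEff[[from]] <- c(uniEff[[from]], effCode[[tr$effect[k]]])
    } else {
      if (bindTo[from] >= 0)
        stop("engine supports one bimolecular transition per state")
      bindTo[from] <- to - 1L
      konVol[from] <- tr$rate[k] / AVOGADRO * 1e15   # M^-1 s^-1 -> um^3/s
    }
  }
  list(nStates = n, uniTo = uniTo, uniRate = uniRate, uniEffect = uniEff,
       bindTo = as.integer(bindTo), bindKonVol = konVol)
}

#' Run one Monte Carlo reaction-diffusion simulation seed
#'
#' Propagates \code{nMolecules} glutamate particles through the scene for
#' \code{nIterations} steps of \code{dt} microseconds. All mesh surfaces are
#' reflective; surface molecules bind, unbind, translocate or transition
#' according to their schemes. Deterministic for a fixed seed.
#'
#' @param scene a populated \code{\linkS4class{Scene}}.
#' @param schemes named list of \code{KineticScheme}, one per species present
#'   (e.g. \code{list(GLT = transporterScheme(applyQ10 = TRUE))}).
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param seed integer RNG seed for this run.
#' @return A \code{\linkS4class{SimResult}}.
#' @export
runSimulation <- function(scene, schemes, config = simConfig(), seed = 1L) {
  validObject(config)
  pops <- scene@populations
  if (!config@useReceptors)
    pops <- pops[vapply(pops, function(p) p@species == "GLT", TRUE)]
  species <- unique(vapply(pops, function(p) p@species, ""))
  missing <- setdiff(species, names(schemes))
  if (length(missing))
    stop("no kinetic scheme supplied for species: ",
         paste(missing, collapse = ", "))
  for (s in schemes) validObject(s)

  ## concatenate meshes into one triangle soup
  meshNames <- names(scene@meshes)
  offs <- integer(length(meshNames)); names(offs) <- meshNames
  nvTot <- 0L
  for (nm in meshNames) {
    offs[nm] <- nvTot
    nvTot <- nvTot + nrow(scene@meshes[[nm]]@vertices)
  }
  V <- do.call(rbind, lapply(scene@meshes, function(m) m@vertices))
  F <- do.call(rbind, lapply(meshNames, function(nm)
    scene@meshes[[nm]]@faces - 1L + offs[nm]))
  triOff <- cumsum(c(0L, vapply(meshNames, function(nm)
    nrow(scene@meshes[[nm]]@faces), 0L)))
  names(triOff) <- c(meshNames, "end")[seq_along(triOff)]

  engSchemes <- lapply(schemes, schemeForEngine)
  engPops <- lapply(pops, function(p) {
    hostIdx <- match(p@hostRole, meshNames)
    if (is.na(hostIdx)) stop("population host mesh not found: ", p@hostRole)
    list(molTri = as.integer(p@triangle - 1L + triOff[hostIdx]),
         molPos = p@positions, tileArea = p@tileArea,
         schemeId = match(p@species, names(schemes)) - 1L)
  })

  cleft <- scene@cleft
  relZ <- if (!is.null(cleft$zmin)) cleft$zmin + 1e-3 else 0
  eng <- .mcRun(V, F, unname(engPops), unname(engSchemes), list(
    dt = config@dt * 1e-6, nIter = as.integer(config@nIterations),
    nMol = as.integer(config@nMolecules),
    dCleft = config@dCleft * CM2_TO_UM2,
    dExtra = config@dExtra * CM2_TO_UM2,
    half = scene@spec@worldEdge / 2,
    cleftR = if (is.null(cleft$radius)) 0 else cleft$radius,
    cleftZmin = if (is.null(cleft$zmin)) 0 else cleft$zmin,
    cleftZmax = if (is.null(cleft$zmax)) 0 else cleft$zmax,
    releaseMode = if (config@releaseMode == "point") 0L else 1L,
    releasePos = c(0, 0, relZ),
    recordStride = as.integer(config@recordStride),
    seed = as.double(seed), maxReflect = 10L))

  counts <- as.data.frame(eng$counts)
  names(counts) <- c("freeCleft", "freeExtra", "bound", "translocated")
  cum <- eng$cumulative
  ## sum reaction tallies over transporter populations
  glt <- which(vapply(pops, function(p) p@species == "GLT", TRUE))
  pick <- function(j) if (length(glt))
    rowSums(cum[, 3 * (glt - 1) + j, drop = FALSE]) else numeric(nrow(cum))
  cumulative <- data.frame(binding = pick(1), unbinding = pick(2),
                           translocation = pick(3))
  time <- seq(0, config@nIterations, by = config@recordStride) *
    config@dt * 1e-3     # ms
  res <- new("SimResult", time = time, counts = counts,
             cumulative = cumulative, nMolecules = config@nMolecules,
             seed = as.integer(seed),
             configHash = configHash(scene, schemes, config),
             clamped = eng$clamped)
  attr(res, "finalPos") <- eng$finalPos
  attr(res, "finalStatus") <- eng$finalStatus
  res
}

#' Run a range of seeds and aggregate
#'
#' @param scene,schemes,config as in \code{\link{runSimulation}}.
#' @param seeds integer vector of seeds.
#' @return A list of \code{SimResult} (one per seed).
#' @export
runSeeds <- function(scene, schemes, config = simConfig(),
                     seeds = seq_len(config@nSeeds)) {
  lapply(seeds, function(s) runSimulation(scene, schemes, config, seed = s))
}

#' Average simulation seeds
#'
#' Pointwise mean and standard error (sample SD / sqrt(n)) of every recorded
#' series across seeds sharing a provenance hash.
#'
#' @param results list of \code{\linkS4class{SimResult}}.
#' @return A \code{\linkS4class{SeedAggregate}}.
#' @export
aggregateSeeds <- function(results) {
  stopifnot(length(results) >= 1L)
  hashes <- vapply(results, function(r) r@configHash, "")
  if (length(unique(hashes)) != 1L)
    stop("cannot aggregate: results carry different config hashes")
  series <- lapply(results, function(r) cbind(r@counts, r@cumulative))
  arr <- simplify2array(lapply(series, as.matrix))
  mu <- apply(arr, c(1, 2), mean)
  n <- length(results)
  if (n == 1L) {
    warning("single seed: SEM reported as 0")
    se <- mu * 0
  } else {
    se <- apply(arr, c(1, 2), sd) / sqrt(n)
  }
  new("SeedAggregate", time = results[[1L]]@time,
      mean = as.data.frame(mu), sem = as.data.frame(se), nSeeds = n,
      configHash = hashes[1L])
}

#' Temporal centroid of a recorded count series
#'
#' First temporal moment \code{sum(t * n) / sum(n)} of a series such as the
#' free-glutamate count in the cleft; the summary statistic for clearance
#' speed.
#'
#' @param result a \code{SimResult} (or \code{SeedAggregate}).
#' @param series column name, e.g. \code{"freeCleft"} or \code{"freeExtra"}.
#' @return Centroid in ms.
#' @export
countCentroid <- function(result, series = "freeCleft") {
  x <- if (is(result, "SeedAggregate")) result@mean[[series]]
       else result@counts[[series]]
  if (sum(x) == 0) stop("series is identically zero")
  sum(result@time * x) / sum(x)
}

#' Glutamate concentration time course in a region
#'
#' Converts a particle-count series into molar concentration:
#' \code{count / (N_A * volume)}.
#'
#' @param result a \code{SimResult}.
#' @param volumeUm3 region volume (um^3).
#' @param series count column name.
#' @return Numeric vector of concentrations (M) on the result's time base.
#' @export
concentrationTimecourse <- function(result, volumeUm3,
                                    series = "freeCleft") {
  stopifnot(volumeUm3 > 0)
  litres <- volumeUm3 * 1e-15
  result@counts[[series]] / (AVOGADRO * litres)
}

## ---------------------------------------------------------------------------
## Engine calibration
## ---------------------------------------------------------------------------

#' Recover the diffusion coefficient from free Brownian motion
#'
#' Propagates non-interacting particles in an unbounded medium and regresses
#' the mean squared displacement against \code{6 D t} (Einstein relation).
#' A calibration check that the engine's step rule realises the configured
#' diffusion coefficient.
#'
#' @param d diffusion coefficient (um^2/ms).
#' @param nParticles,nSteps ensemble size and step count.
#' @param dtUs time step (us).
#' @param seed RNG seed.
#' @return Fitted D (um^2/ms), with the regression in attribute
#'   \code{"fit"}.
#' @export
estimateFreeDiffusionD <- function(d, nParticles = 1e4, nSteps = 1e3,
                                   dtUs = 10, seed = 1L) {
  stopifnot(d >= 0)
  dtMs <- dtUs * 1e-3
  sigma <- sqrt(2 * d * dtMs)
  rs <- localRNG(seed)
  on.exit(localRNGRestore(rs))
  pos <- matrix(0, nParticles, 3L)
  rec <- seq(0L, nSteps, by = max(1L, nSteps %/% 50L))[-1L]
  msd <- numeric(length(rec)); ri <- 1L
  for (s in seq_len(nSteps)) {
    pos <- pos + matrix(rnorm(nParticles * 3L, sd = sigma), ncol = 3L)
    if (ri <= length(rec) && s == rec[ri]) {
      msd[ri] <- mean(rowSums(pos^2))
      ri <- ri + 1L
    }
  }
  t <- rec * dtMs
  fit <- lm(msd ~ 0 + t)
  est <- unname(coef(fit)[1L]) / 6
  attr(est, "fit") <- fit
  est
}

#' Sealed-box calibration scene
#'
#' A world box whose inner walls carry surface molecules at a given density,
#' with no other compartments: the geometry for the well-mixed calibration of
#' the engine's bimolecular binding probability.
#'
#' @param edge box edge length (um).
#' @param density wall molecule density (um^-2).
#' @param species species label.
#' @param seed placement seed.
#' @return A \code{Scene} (no cleft region).
#' @export
calibrationBoxScene <- function(edge = 1, density = 2000, species = "GLT",
                                seed = 1L) {
  spec <- sceneSpec("control", worldEdge = edge, nAstro = 0,
                    transporterDensity = 0, preVolume = 0, postVolume = 0)
  world <- boxMesh(c(0, 0, 0), rep(edge, 3L), role = "world", inward = TRUE)
  pop <- placeSurfaceMolecules(world, density, species = species, seed = seed)
  pop@hostRole <- "world"
  new("Scene", spec = spec, meshes = list(world = world),
      populations = setNames(list(pop), species),
      cleft = list(radius = 0, zmin = 0, zmax = 0), seed = as.integer(seed))
}

#' Well-mixed binding oracle for the sealed-box calibration
#'
#' Deterministic mass-action solution for ligand binding to wall sites in a
#' sealed box (no translocation): counts obey
#' \code{dB/dt = kOn' (S - B)(G - B)/V - kOff B}, integrated with RK4.
#'
#' @param kOn binding rate (M^-1 s^-1).
#' @param kOff unbinding rate (s^-1).
#' @param nSites number of wall sites.
#' @param nLigand number of ligand molecules.
#' @param volumeUm3 box volume (um^3).
#' @param tMaxMs,dtMs time span and step (ms).
#' @return data.frame with \code{time} (ms) and \code{bound} (expected count).
#' @export
wellMixedBindingODE <- function(kOn, kOff, nSites, nLigand, volumeUm3,
                                tMaxMs = 50, dtMs = 0.01) {
  konVol <- kOn / AVOGADRO * 1e15          # um^3/s per molecule
  f <- function(B) konVol * (nSites - B) * (nLigand - B) / volumeUm3 / 1e3 -
    kOff * B / 1e3                          # per ms
  n <- round(tMaxMs / dtMs)
  B <- numeric(n + 1L)
  for (k in seq_len(n)) {
    b <- B[k]
    k1 <- f(b); k2 <- f(b + dtMs / 2 * k1); k3 <- f(b + dtMs / 2 * k2)
    k4 <- f(b + dtMs * k3)
    B[k + 1L] <- b + dtMs / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(time = dtMs * (0:n), bound = B)
}

#' Audit that no particle sits inside a solid compartment
#'
#' Ray-casting point-in-mesh test of final free-particle positions against
#' every watertight compartment of the scene.
#'
#' @param result a \code{SimResult} (carrying final positions).
#' @param scene the scene it was run in.
#' @return Number of offending particles (0 for a clean run).
#' @export
auditParticlePositions <- function(result, scene) {
  pos <- attr(result, "finalPos")
  st <- attr(result, "finalStatus")
  if (is.null(pos)) stop("result carries no final positions")
  free <- pos[st == 0L, , drop = FALSE]
  if (nrow(free) == 0L) return(0L)
  bad <- 0L
  for (nm in setdiff(names(scene@meshes), c("world", "PSD"))) {
    m <- scene@meshes[[nm]]
    bad <- bad + sum(.pointsInMesh(m@vertices, m@faces - 1L, free))
  }
  bad
}

#' @describeIn SimResult-class compact display
#' @param object a \code{SimResult}
#' @export
setMethod("show", "SimResult", function(object) {
  n <- length(object@time)
  cat(sprintf(
    "SimResult: %d molecules, %d recorded steps over %.3g ms (seed %d)\n",
    object@nMolecules, n, max(object@time), object@seed))
  cat(sprintf("  final: cleft %d, neuropil %d, bound %d, translocated %d\n",
              object@counts$freeCleft[n], object@counts$freeExtra[n],
              object@counts$bound[n], object@counts$translocated[n]))
  cat(sprintf("  cumulative: %g bindings, %g unbindings, %g translocations\n",
              object@cumulative$binding[n], object@cumulative$unbinding[n],
              object@cumulative$translocation[n]))
})

#' @describeIn SeedAggregate-class compact display
#' @param object a \code{SeedAggregate}
#' @export
setMethod("show", "SeedAggregate", function(object) {
  cat(sprintf("SeedAggregate over %d seeds, %d recorded steps\n",
              object@nSeeds, length(object@time)))
})
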