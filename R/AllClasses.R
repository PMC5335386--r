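#' @import methods
#' @importFrom stats sd rnorm runif rpois coef lm nls nls.control optim
#'   fft convolve t.test var approx integrate setNames qnorm pchisq
#'   residuals
#' @importFrom utils head tail write.csv read.csv write.table modifyList
#' @useDynLib GluClear, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Geometry classes
## ---------------------------------------------------------------------------

#' Triangulated surface mesh
#'
#' A triangle mesh in micrometre units. Vertices are an n x 3 numeric matrix,
#' faces an m x 3 integer matrix of 1-based vertex indices, and \code{role}
#' labels the compartment the mesh represents (\code{"presynaptic"},
#' \code{"postsynaptic"}, \code{"PSD"}, \code{"astrocyte"} or \code{"world"}).
#'
#' @slot vertices numeric matrix, n x 3, coordinates in micrometres.
#' @slot faces integer matrix, m x 3, 1-based indices into \code{vertices}.
#' @slot role character scalar compartment label.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix", role = "character"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3), role = "unlabelled"))

setValidity("TriMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of vertex range")
    a <- triangleAreas(v, f)
    if (any(a <= 1e-16))
      return(sprintf("degenerate (zero-area) triangle at face %d",
                     which(a <= 1e-16)[1L]))
  }
  if (length(object@role) != 1L) return("role must be a single string")
  TRUE
})

#' Specification of a simplified synapse scene
#'
#' Scalar parameters describing the simplified synapse/astrocyte geometry:
#' a cubic world, two apposed terminals separated by a thin cleft, a PSD disc
#' on the postsynaptic cleft face, and thin astrocytic sheets arranged around
#' the cleft axis. Defaults are the control condition; see
#' \code{\link{sceneSpec}} for the named presets.
#'
#' @slot worldEdge world cube edge length (um).
#' @slot preVolume,preRadius presynaptic terminal volume (um^3) and radius (um).
#' @slot postVolume,postRadius postsynaptic terminal volume (um^3) and radius (um).
#' @slot cleftHeight synaptic cleft height (nm).
#' @slot psdArea PSD disc area (um^2).
#' @slot nAstro number of astrocytic processes.
#' @slot astroArea surface area of one astrocytic process (um^2).
#' @slot astroDistance nearest PSD-to-astrocyte distance (nm).
#' @slot transporterDensity glutamate transporter surface density (um^-2).
#' @slot gluaPsdDensity,glunPsdDensity GluA/GluN density on the PSD (um^-2).
#' @slot gluaExtraDensity,glunExtraDensity extrasynaptic GluA/GluN density (um^-2).
#' @export
setClass("SceneSpec",
  representation(worldEdge = "numeric",
                 preVolume = "numeric", preRadius = "numeric",
                 postVolume = "numeric", postRadius = "numeric",
                 cleftHeight = "numeric", psdArea = "numeric",
                 nAstro = "numeric", astroArea = "numeric",
                 astroDistance = "numeric",
                 transporterDensity = "numeric",
                 gluaPsdDensity = "numeric", glunPsdDensity = "numeric",
                 gluaExtraDensity = "numeric", glunExtraDensity = "numeric"),
  prototype(worldEdge = 1, preVolume = 0.079, preRadius = 0.27,
            postVolume = 0.040, postRadius = 0.27, cleftHeight = 20,
            psdArea = 0.10, nAstro = 2, astroArea = 0.69,
            astroDistance = 116, transporterDensity = 10800,
            gluaPsdDensity = 200, glunPsdDensity = 300,
            gluaExtraDensity = 40, glunExtraDensity = 60))

setValidity("SceneSpec", function(object) {
  nn <- c("worldEdge", "preVolume", "preRadius", "postVolume", "postRadius",
          "cleftHeight", "psdArea", "nAstro", "astroArea", "astroDistance",
          "transporterDensity", "gluaPsdDensity", "glunPsdDensity",
          "gluaExtraDensity", "glunExtraDensity")
  for (s in nn) {
    x <- slot(object, s)
    if (length(x) != 1L || !is.finite(x)) return(sprintf("%s must be a finite scalar", s))
    if (x < 0) return(sprintf("%s must be >= 0", s))
  }
  if (object@worldEdge <= 0) return("worldEdge must be > 0")
  if (object@cleftHeight * 1e-3 >= object@preRadius ||
      object@cleftHeight * 1e-3 >= object@postRadius)
    return("cleft height must be smaller than both terminal radii")
  if (object@nAstro != round(object@nAstro)) return("nAstro must be an integer")
  TRUE
})

#' Surface molecule population
#'
#' Molecules placed on a host mesh: each molecule sits on a triangle at
#' barycentric coordinates, in a kinetic state of its scheme.
#'
#' @slot species species label (e.g. \code{"GLT"}).
#' @slot hostRole role label of the host mesh.
#' @slot triangle integer vector of host triangle indices.
#' @slot bary numeric matrix (n x 3) of barycentric coordinates.
#' @slot positions numeric matrix (n x 3) of Cartesian positions (um).
#' @slot tileArea per-molecule surface tile area (um^2).
#' @export
setClass("SurfacePopulation",
  representation(species = "character", hostRole = "character",
                 triangle = "integer", bary = "matrix",
                 positions = "matrix", tileArea = "numeric"))

#' A populated simulation scene
#'
#' Compartment meshes plus surface molecule populations and the cleft-region
#' definition (a cylinder between the terminal cleft faces, used to classify
#' particles into cleft vs extracellular neuropil).
#'
#' @slot spec the \code{SceneSpec} the scene was built from.
#' @slot meshes named list of \code{TriMesh} compartments.
#' @slot populations named list of \code{SurfacePopulation}.
#' @slot cleft list with \code{radius}, \code{zmin}, \code{zmax} (um).
#' @slot seed integer seed used for molecule placement.
#' @export
setClass("Scene",
  representation(spec = "SceneSpec", meshes = "list", populations = "list",
                 cleft = "list", seed = "integer"))

## ---------------------------------------------------------------------------
## Kinetics classes
## ---------------------------------------------------------------------------

#' Ligand-driven Markov kinetic scheme
#'
#' States connected by unimolecular (rate s^-1) or bimolecular
#' (rate M^-1 s^-1, naming a ligand) transitions. Bimolecular transitions may
#' consume a ligand molecule; unimolecular transitions may release or
#' sequester the bound ligand (side effects used by the particle engine).
#'
#' @slot states character vector of state names.
#' @slot transitions data.frame with columns \code{from}, \code{to},
#'   \code{rate}, \code{ligand} (NA for unimolecular), \code{effect}
#'   (\code{"none"}, \code{"consume"}, \code{"release"}, \code{"sequester"}).
#' @slot conducting character vector of conducting state names.
#' @export
setClass("KineticScheme",
  representation(states = "character", transitions = "data.frame",
                 conducting = "character"))

setValidity("KineticScheme", function(object) {
  tr <- object@transitions
  need <- c("from", "to", "rate", "ligand", "effect")
  if (!all(need %in% names(tr))) return("transitions must have columns from/to/rate/ligand/effect")
  if (any(!tr$from %in% object@states) || any(!tr$to %in% object@states))
    return("transition endpoints must be declared states")
  if (any(tr$rate < 0)) return("rates must be >= 0")
  bim <- !is.na(tr$ligand)
  if (any(bim & tr$effect == "release"))
    return("bimolecular transitions cannot release ligand")
  if (any(!tr$effect %in% c("none", "consume", "release", "sequester")))
    return("unknown transition effect")
  if (!all(object@conducting %in% object@states))
    return("conducting states must be declared states")
  ## connectivity of the undirected state graph
  if (length(object@states) > 1L) {
    adj <- unique(rbind(cbind(tr$from, tr$to), cbind(tr$to, tr$from)))
    reach <- object@states[1L]
    repeat {
      nxt <- unique(c(reach, adj[adj[, 1L] %in% reach, 2L]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (!all(object@states %in% reach)) return("state graph is not connected")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Monte Carlo simulation classes
## ---------------------------------------------------------------------------

#' Monte Carlo simulation configuration
#'
#' Engine settings for the particle-based reaction-diffusion simulation.
#' Defaults follow the reference protocol: 10 us steps, 5,000 iterations
#' (50 ms span), 2,000 released glutamate molecules, cleft diffusion
#' coefficient 3.3e-6 cm^2/s and extracellular (tortuosity-corrected)
#' coefficient 1.41e-6 cm^2/s.
#'
#' @slot dt time step (us).
#' @slot nIterations number of steps.
#' @slot nMolecules number of released glutamate molecules.
#' @slot nSeeds default number of seeds for multi-seed runs.
#' @slot dCleft,dExtra diffusion coefficients (cm^2/s) inside/outside cleft.
#' @slot releaseMode \code{"point"} (cleft axis, 1 nm off the presynaptic
#'   face) or \code{"uniform"} (uniform in free space; calibration runs).
#' @slot recordStride record every k-th step.
#' @slot useReceptors logical; populate and simulate receptor populations.
#' @slot tortuosity named numeric vector, stored as metadata only
#'   (lambda_total, lambda_g, lambda_v, lambda_x, occupied_fraction).
#' @export
setClass("SimConfig",
  representation(dt = "numeric", nIterations = "numeric",
                 nMolecules = "numeric", nSeeds = "numeric",
                 dCleft = "numeric", dExtra = "numeric",
                 releaseMode = "character", recordStride = "numeric",
                 useReceptors = "logical", tortuosity = "numeric"),
  prototype(dt = 10, nIterations = 5000, nMolecules = 2000, nSeeds = 300,
            dCleft = 3.3e-6, dExtra = 1.41e-6, releaseMode = "point",
            recordStride = 1, useReceptors = FALSE,
            tortuosity = c(lambda_total = 1.6, lambda_g = 1.48,
                           lambda_v = 1.38, lambda_x = 1.11,
                           occupied_fraction = 0.18)))

setValidity("SimConfig", function(object) {
  if (object@dt <= 0 || object@nIterations <= 0 || object@nMolecules <= 0 ||
      object@nSeeds <= 0)
    return("dt, nIterations, nMolecules and nSeeds must be > 0")
  if (object@dCleft <= 0 || object@dExtra <= 0) return("D values must be > 0")
  if (!object@releaseMode %in% c("point", "uniform"))
    return("releaseMode must be 'point' or 'uniform'")
  if (object@recordStride < 1) return("recordStride must be >= 1")
  TRUE
})

#' Result of one Monte Carlo simulation seed
#'
#' Per-recorded-step particle tallies and cumulative reaction counts.
#' At every step \code{freeCleft + freeExtra + bound + translocated}
#' equals the number of released molecules.
#'
#' @slot time recorded time base (ms).
#' @slot counts data.frame: \code{freeCleft}, \code{freeExtra}, \code{bound},
#'   \code{translocated} particle counts per recorded step.
#' @slot cumulative data.frame: cumulative \code{binding}, \code{unbinding},
#'   \code{translocation} reaction tallies.
#' @slot nMolecules number of released molecules.
#' @slot seed RNG seed of this run.
#' @slot configHash hash of (scene, scheme, config) provenance.
#' @slot clamped number of particle-steps clamped at the reflection cap.
#' @export
setClass("SimResult",
  representation(time = "numeric", counts = "data.frame",
                 cumulative = "data.frame", nMolecules = "numeric",
                 seed = "integer", configHash = "character",
                 clamped = "numeric"))

setValidity("SimResult", function(object) {
  tot <- rowSums(object@counts[, c("freeCleft", "freeExtra", "bound",
                                   "translocated")])
  if (any(tot != object@nMolecules))
    return("particle conservation violated: counts do not sum to nMolecules")
  cum <- as.matrix(object@cumulative)
  if (nrow(cum) > 1L && any(diff(cum) < 0))
    return("cumulative tallies must be non-decreasing")
  TRUE
})

#' Mean and SEM of simulation series across seeds
#'
#' @slot time recorded time base (ms).
#' @slot mean,sem data.frames of per-step means and standard errors for each
#'   recorded series.
#' @slot nSeeds number of aggregated seeds.
#' @slot configHash shared provenance hash.
#' @export
setClass("SeedAggregate",
  representation(time = "numeric", mean = "data.frame", sem = "data.frame",
                 nSeeds = "numeric", configHash = "character"))

## ---------------------------------------------------------------------------
## Electrophysiology / imaging classes
## ---------------------------------------------------------------------------

#' Sampled membrane current trace
#'
#' @slot samples current samples (pA).
#' @slot rateKHz sampling rate (kHz, default 10).
#' @slot stimMs stimulus time (ms from record start).
#' @export
setClass("CurrentTrace",
  representation(samples = "numeric", rateKHz = "numeric", stimMs = "numeric"),
  prototype(rateKHz = 10, stimMs = 0))

setValidity("CurrentTrace", function(object) {
  if (object@rateKHz <= 0) return("rateKHz must be > 0")
  if (length(object@samples) < 2L) return("trace must hold at least 2 samples")
  dur <- (length(object@samples) - 1) / object@rateKHz
  if (object@stimMs < 0 || object@stimMs > dur)
    return("stimulus time must lie within the record")
  TRUE
})

#' Line-scan kymograph
#'
#' Fluorescence intensity sampled along a scan line over time.
#'
#' @slot intensity numeric matrix, position x time (rows are pixels).
#' @slot pixelUm pixel size along the line (um).
#' @slot lineRateHz line rate (Hz, default 625).
#' @slot puffLine 1-based line (column) index of the pressure application.
#' @export
setClass("Kymograph",
  representation(intensity = "matrix", pixelUm = "numeric",
                 lineRateHz = "numeric", puffLine = "numeric"),
  prototype(lineRateHz = 625))

setValidity("Kymograph", function(object) {
  if (object@lineRateHz <= 0) return("lineRateHz must be > 0")
  if (object@pixelUm <= 0) return("pixelUm must be > 0")
  if (object@puffLine < 1 || object@puffLine > ncol(object@intensity))
    return("puffLine must lie within the record")
  TRUE
})
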