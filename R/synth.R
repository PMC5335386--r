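## Seeded synthetic-data generators for every input class the analyses
## consume: fSTC pairs built as clearance (*) filter with paired-pulse
## facilitation and Gaussian noise, point-source diffusion kymographs with
## Poisson photon noise, and synapse-geometry specifications drawn from the
## reconstruction statistics. Every generator is a pure function of
## (spec, seed) and returns its ground truth alongside the data.

#' Synthetic-data specification
#'
#' Defaults emulate the control recording condition: a biexponential
#' clearance waveform whose fitted fSTC decay matches the control kinetics
#' (tau_fast ~ 5.3 ms, tau_slow ~ 18.3 ms) and whose centroid is ~16.5 ms;
#' a gamma-kernel (shape 2) filter with ~2 ms time-to-peak; 1.5-fold
#' paired-pulse facilitation at 100 ms; 10 kHz sampling; line scans at
#' 625 Hz.
#'
#' @param seed default RNG seed.
#' @param rateKHz current sampling rate (kHz).
#' @param durationMs record length (ms).
#' @param stimMs stimulus time (ms).
#' @param amplitudePa fSTC peak amplitude (pA; negative = inward).
#' @param noiseSdPa Gaussian current noise SD (pA).
#' @param clearTauFast,clearTauSlow,clearFFast clearance biexponential.
#' @param filterShape,filterScaleMs gamma filter kernel parameters.
#' @param facilitation paired-pulse facilitation factor (>= 1).
#' @param ipiMs inter-pulse interval (ms).
#' @param kymoD diffusion coefficient for kymographs (um^2/ms).
#' @param kymoPixelUm,kymoNx,kymoLineRateHz,kymoDurationS,kymoPuffS kymograph
#'   geometry and timing.
#' @param kymoSourceUm out-of-line source distance (um).
#' @param kymoPeakCounts photon counts at the first profile peak (Poisson
#'   noise scale); \code{Inf} disables noise.
#' @param kymoBgCounts background counts per pixel.
#' @return A list (the synthetic-data spec).
#' @export
synthSpec <- function(seed = 1L, rateKHz = 10, durationMs = 500,
                      stimMs = 100, amplitudePa = -27.7, noiseSdPa = 0.3,
                      clearTauFast = 5.5, clearTauSlow = 21,
                      clearFFast = 0.55, filterShape = 2,
                      filterScaleMs = 2.0, facilitation = 1.5, ipiMs = 100,
                      kymoD = 0.38, kymoPixelUm = 0.2, kymoNx = 750L,
                      kymoLineRateHz = 625, kymoDurationS = 8,
                      kymoPuffS = 0.2, kymoSourceUm = 7,
                      kymoPeakCounts = 2000, kymoBgCounts = 20) {
  stopifnot(facilitation >= 1, noiseSdPa >= 0, clearFFast >= 0,
            clearFFast <= 1)
  as.list(environment())
}

## gamma-kernel filter (unit sum) on the trace time base; scale 0 collapses
## to a discrete delta (no distortion)
gammaFilterKernel <- function(rateKHz, shape, scaleMs, lengthMs = 50) {
  t <- seq(0, lengthMs, by = 1 / rateKHz)
  if (scaleMs == 0) return(c(1, rep(0, length(t) - 1L)))
  h <- t^(shape - 1) * exp(-t / scaleMs)
  h / sum(h)
}

#' Synthesize a single/paired fSTC recording pair
#'
#' The fSTC is built as clearance waveform (instantaneous rise,
#' biexponential decay) convolved with a gamma filter kernel, scaled to the
#' requested amplitude; the paired trace adds a facilitated copy at the
#' inter-pulse interval; Gaussian noise is added to both. The ground truth
#' (clearance waveform and its analytic centroid, the filter) is returned
#' for recovery tests.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @param seed RNG seed (defaults to \code{spec$seed}).
#' @return A list: \code{single}, \code{paired} (\code{CurrentTrace}),
#'   \code{truth} (list with \code{clearance}, \code{filter},
#'   \code{clearanceCentroid} in ms, \code{fstcNoiseless}).
#' @export
synthFSTC <- function(spec = synthSpec(), seed = spec$seed) {
  rs <- localRNG(seed)
  on.exit(localRNGRestore(rs))
  dt <- 1 / spec$rateKHz
  n <- round(spec$durationMs * spec$rateKHz) + 1L
  t <- (seq_len(n) - 1L) * dt
  tr <- t - spec$stimMs
  clr <- ifelse(tr >= 0,
                spec$clearFFast * exp(-tr / spec$clearTauFast) +
                  (1 - spec$clearFFast) * exp(-tr / spec$clearTauSlow), 0)
  h <- gammaFilterKernel(spec$rateKHz, spec$filterShape, spec$filterScaleMs)
  resp <- convolveCausal(clr, h)
  resp <- resp / max(resp) * spec$amplitudePa
  shift <- round(spec$ipiMs * spec$rateKHz)
  resp2 <- c(rep(0, shift), spec$facilitation * resp[seq_len(n - shift)])
  single <- resp + rnorm(n, sd = spec$noiseSdPa)
  paired <- resp + resp2 + rnorm(n, sd = spec$noiseSdPa)
  tf <- spec$clearTauFast; ts <- spec$clearTauSlow; f <- spec$clearFFast
  cen <- (f * tf^2 + (1 - f) * ts^2) / (f * tf + (1 - f) * ts)
  list(single = currentTrace(single, spec$rateKHz, spec$stimMs),
       paired = currentTrace(paired, spec$rateKHz, spec$stimMs),
       truth = list(clearance = clr, filter = h, clearanceCentroid = cen,
                    fstcNoiseless = resp))
}

#' Synthesize a line-scan kymograph of point-source diffusion
#'
#' Analytic 3D Gaussian spread of an instantaneous point source placed
#' \code{kymoSourceUm} off the scan line, sampled at the line rate, with
#' optional Poisson photon noise and a flat background; pre-puff baseline
#' lines are included. The in-line profile at time t is Gaussian with
#' \code{gamma^2 = 4 D t} exactly.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @param seed RNG seed (defaults to \code{spec$seed}).
#' @return A list: \code{kymo} (a \code{Kymograph}), \code{truth} (list with
#'   \code{D} in um^2/ms).
#' @export
synthKymograph <- function(spec = synthSpec(), seed = spec$seed) {
  stopifnot(spec$kymoD > 0)
  rs <- localRNG(seed)
  on.exit(localRNGRestore(rs))
  nx <- spec$kymoNx
  nt <- round(spec$kymoDurationS * spec$kymoLineRateHz)
  puff <- round(spec$kymoPuffS * spec$kymoLineRateHz) + 1L
  x <- (seq_len(nx) - 1L) * spec$kymoPixelUm
  x0 <- mean(x)
  tMs <- (seq_len(nt) - puff) / spec$kymoLineRateHz * 1000
  img <- matrix(spec$kymoBgCounts, nx, nt)
  live <- which(tMs > 0)
  ## normalize so the first analysed profile (~150 ms) peaks at
  ## kymoPeakCounts
  tRef <- 150
  aRef <- (4 * pi * spec$kymoD * tRef)^(-1.5) *
    exp(-spec$kymoSourceUm^2 / (4 * spec$kymoD * tRef))
  amp <- if (spec$kymoPeakCounts == 0) 0
         else if (is.finite(spec$kymoPeakCounts)) spec$kymoPeakCounts / aRef
         else 1 / aRef
  for (j in live) {
    tt <- tMs[j]
    prof <- amp * (4 * pi * spec$kymoD * tt)^(-1.5) *
      exp(-((x - x0)^2 + spec$kymoSourceUm^2) / (4 * spec$kymoD * tt))
    img[, j] <- img[, j] + prof
  }
  if (is.finite(spec$kymoPeakCounts) && spec$kymoPeakCounts > 0)
    img <- matrix(rpois(length(img), img), nx, nt)
  list(kymo = kymograph(img, pixelUm = spec$kymoPixelUm,
                        lineRateHz = spec$kymoLineRateHz, puffLine = puff),
       truth = list(D = spec$kymoD))
}

#' Reconstruction statistics of synapse geometry
#'
#' Mean and SD of the geometric descriptors measured across reconstructed
#' synapses (per condition), used by \code{\link{synthSceneSpecs}}.
#'
#' @param condition \code{"control"} or \code{"tfllr"}.
#' @return data.frame with columns \code{field}, \code{mean}, \code{sd},
#'   \code{min} (physical truncation minimum).
#' @export
geometryStats <- function(condition = c("control", "tfllr")) {
  condition <- match.arg(condition)
  if (condition == "control")
    data.frame(
      field = c("psdArea", "preVolume", "postVolume", "nAstro", "astroArea",
                "astroDistance"),
      mean = c(0.10, 0.08, 0.04, 2.25, 0.91, 116.5),
      sd = c(0.11, 0.08, 0.04, 1.54, 0.43, 55.4),
      min = c(0.01, 0.005, 0.005, 1, 0.2, 0))
  else
    data.frame(
      field = c("psdArea", "preVolume", "postVolume", "nAstro", "astroArea",
                "astroDistance"),
      mean = c(0.08, 0.06, 0.03, 4.23, 0.58, 190.9),
      sd = c(0.05, 0.03, 0.02, 2.38, 0.15, 74.6),
      min = c(0.01, 0.005, 0.005, 1, 0.2, 0))
}

## truncated-normal sampling by rejection (simple; truncation is mild here)
rtruncN <- function(n, mean, sd, min) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= min])
  }
  out[seq_len(n)]
}

#' Draw synthetic scene specifications from geometry statistics
#'
#' Samples each geometric field from a truncated normal with the
#' reconstruction mean and SD (physical minima enforced by truncation);
#' astrocytic process counts are rounded to integers >= 1. Terminal radii
#' are derived from the sampled volumes (sphere-equivalent) and capped so
#' the terminals clear the astrocytic sheets; draws whose field
#' combination cannot be realised as a scene (sheets inside a terminal or
#' outside the world) are redrawn, i.e. the distribution is additionally
#' truncated to geometrically feasible synapses.
#'
#' @param stats data.frame as returned by \code{\link{geometryStats}}.
#' @param n number of specs to draw.
#' @param seed RNG seed.
#' @return List of \code{\linkS4class{SceneSpec}}.
#' @export
synthSceneSpecs <- function(stats = geometryStats("control"), n = 1,
                            seed = 1L) {
  stopifnot(n >= 1)
  rs <- localRNG(seed)
  on.exit(localRNGRestore(rs))
  drawOne <- function() {
    args <- setNames(lapply(seq_len(nrow(stats)), function(i)
      rtruncN(1L, stats$mean[i], stats$sd[i], stats$min[i])), stats$field)
    if (!is.null(args$nAstro)) args$nAstro <- max(1, round(args$nAstro))
    a <- sqrt(args$psdArea / pi)
    ## sheets must clear the apposition: floor the distance accordingly
    args$astroDistance <- max(args$astroDistance, 120 * a)
    rho <- a + args$astroDistance * 1e-3
    fitTerminal <- function(vol) {
      r <- max(min((3 * vol / (4 * pi))^(1 / 3) * 1.4, 0.9 * rho), a * 1.02)
      ## clamp the volume to what the capped truncated sphere can hold
      h <- r - sqrt(max(r^2 - a^2, 0))
      vmesh <- 4 / 3 * pi * r^3 - pi * h^2 * (3 * r - h) / 3
      list(radius = r, volume = min(vol, 0.9 * vmesh))
    }
    if (!is.null(args$preVolume)) {
      ft <- fitTerminal(args$preVolume)
      args$preRadius <- ft$radius; args$preVolume <- ft$volume
    }
    if (!is.null(args$postVolume)) {
      ft <- fitTerminal(args$postVolume)
      args$postRadius <- ft$radius; args$postVolume <- ft$volume
    }
    do.call(sceneSpec, c(list(condition = "control"), args))
  }
  feasible <- function(s) {
    a <- sqrt(s@psdArea / pi)
    rho <- a + s@astroDistance * 1e-3
    ## scaled radial extent of a truncated sphere rescaled to its volume
    scaledExtent <- function(vol, r) {
      h <- r - sqrt(max(r^2 - a^2, 0))
      vmesh <- 4 / 3 * pi * r^3 - pi * h^2 * (3 * r - h) / 3
      r * (vol / vmesh)^(1 / 3)
    }
    if (scaledExtent(s@preVolume, s@preRadius) * 1.02 >= rho) return(FALSE)
    if (scaledExtent(s@postVolume, s@postRadius) * 1.02 >= rho) return(FALSE)
    dims <- tryCatch(astroSheetDims(s@astroArea, rho, as.integer(s@nAstro),
                                    s@worldEdge),
                     error = function(e) NULL)
    if (is.null(dims)) return(FALSE)
    if (dims$H / 2 > 0.49 * s@worldEdge) return(FALSE)
    TRUE
  }
  out <- vector("list", n)
  for (k in seq_len(n)) {
    for (try in 1:200) {
      s <- drawOne()
      if (feasible(s)) break
      if (try == 200) stop("could not draw a feasible scene specification")
    }
    out[[k]] <- s
  }
  out
}
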