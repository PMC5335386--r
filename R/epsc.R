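## Deterministic kinetic EPSC simulations: receptor-state occupancies driven
## by fast glutamate transients with a constant competitive antagonist, RK4
## integration at 5 us steps; block-ratio contours and train summation.

#' Glutamate transient descriptor
#'
#' Instantaneously rising, monoexponentially decaying free glutamate
#' concentration at the receptors.
#'
#' @param peakM peak concentration (M).
#' @param tauMs decay time constant (ms).
#' @param onsetMs onset time (ms).
#' @return A list describing the transient.
#' @export
glutTransient <- function(peakM, tauMs, onsetMs = 0) {
  stopifnot(peakM >= 0, tauMs > 0)
  list(peakM = peakM, tauMs = tauMs, onsetMs = onsetMs)
}

#' EPSC integration settings
#'
#' @param stepUs RK4 step (us, default 5).
#' @param spanMs simulated span (ms).
#' @param outputMs output sampling interval (ms, default 0.01).
#' @param vHoldMv holding potential (mV, default -70).
#' @param eRevMv reversal potential (mV, default 0).
#' @return A list of settings.
#' @export
epscConfig <- function(stepUs = 5, spanMs = 50, outputMs = 0.01,
                       vHoldMv = -70, eRevMv = 0) {
  stopifnot(stepUs > 0, spanMs > 0, outputMs >= stepUs * 1e-3)
  list(stepUs = stepUs, spanMs = spanMs, outputMs = outputMs,
       vHoldMv = vHoldMv, eRevMv = eRevMv)
}

## stationary distribution of a generator matrix (rates i->j, zero row sums):
## replace one balance equation with the normalization constraint
steadyStateOf <- function(Q) {
  n <- nrow(Q)
  A <- t(Q)
  A[n, ] <- 1
  p <- tryCatch(solve(A, c(rep(0, n - 1L), 1)), error = function(e) {
    ## nearly reducible chain: fall back to least squares on the full system
    qr.coef(qr(rbind(t(Q), rep(1, n)), tol = 1e-300),
            c(rep(0, n), 1))
  })
  p[p < 0] <- 0
  p / sum(p)
}

## split a scheme's generator into a constant part (unimolecular +
## antagonist-bound at fixed concentration) and the per-molar glutamate part
epscGenerators <- function(scheme, antagonistM,
                           glutLigand = "Glu") {
  states <- scheme@states
  n <- length(states)
  Q0 <- matrix(0, n, n); Qg <- matrix(0, n, n)
  tr <- scheme@transitions
  for (k in seq_len(nrow(tr))) {
    i <- match(tr$from[k], states); j <- match(tr$to[k], states)
    if (is.na(tr$ligand[k])) {
      Q0[i, j] <- Q0[i, j] + tr$rate[k]
    } else if (tr$ligand[k] == glutLigand) {
      Qg[i, j] <- Qg[i, j] + tr$rate[k]
    } else {
      Q0[i, j] <- Q0[i, j] + tr$rate[k] * antagonistM
    }
  }
  diag(Q0) <- diag(Q0) - rowSums(Q0)
  diag(Qg) <- diag(Qg) - rowSums(Qg)
  list(Q0 = Q0, Qg = Qg)
}

#' Simulate a kinetic EPSC
#'
#' Integrates the receptor occupancies under a glutamate transient (plus a
#' constant competitive antagonist concentration) with fixed-step RK4 and
#' returns the conducting (open) occupancy trace; the current is the open
#' occupancy scaled by the driving force.
#'
#' @param scheme a \code{\linkS4class{KineticScheme}} whose bimolecular
#'   transitions name \code{"Glu"} for glutamate; any other ligand name is
#'   treated as the antagonist (constant bath concentration).
#' @param transient a \code{\link{glutTransient}}, or a list of them for a
#'   train.
#' @param antagonistM antagonist concentration (M).
#' @param config an \code{\link{epscConfig}}.
#' @param p0 initial occupancy (defaults to all receptors unbound, state 1).
#' @return A list: \code{timeMs}, \code{open} (conducting occupancy),
#'   \code{current} (normalized, \code{open * (vHold - eRev)} in mV units),
#'   \code{peak} (peak open occupancy), \code{occ} (full occupancy matrix),
#'   \code{maxLeak}.
#' @details When \code{p0} is not given, receptors start at the
#'   glutamate-free steady state of the scheme under the (bath-applied)
#'   antagonist, i.e. pre-equilibrated with the antagonist.
#' @export
simulateEPSC <- function(scheme, transient, antagonistM = 0,
                         config = epscConfig(), p0 = NULL) {
  validObject(scheme)
  if (!length(scheme@conducting))
    stop("scheme declares no conducting state")
  if (antagonistM > 0) {
    lig <- unique(stats::na.omit(scheme@transitions$ligand))
    if (!length(setdiff(lig, "Glu")))
      stop("antagonist > 0 but the scheme has no antagonist-binding states")
  }
  if (!is.null(transient$peakM)) transient <- list(transient)
  onsets <- vapply(transient, `[[`, 0, "onsetMs") * 1e-3
  peaks <- vapply(transient, `[[`, 0, "peakM")
  taus <- vapply(transient, `[[`, 0, "tauMs") * 1e-3
  if (length(unique(peaks)) > 1L || length(unique(taus)) > 1L)
    stop("all pulses of a train share one peak and decay")
  gen <- epscGenerators(scheme, antagonistM)
  n <- length(scheme@states)
  if (is.null(p0)) p0 <- steadyStateOf(gen$Q0)
  dt <- config$stepUs * 1e-6
  nSteps <- round(config$spanMs * 1e-3 / dt)
  stride <- max(1L, round(config$outputMs * 1e-3 / dt))
  out <- .rk4Occupancy(gen$Q0, gen$Qg, onsets, peaks[1L], taus[1L],
                       dt, nSteps, stride, p0)
  occ <- out$occ
  colnames(occ) <- scheme@states
  open <- rowSums(occ[, scheme@conducting, drop = FALSE])
  timeMs <- seq(0, nSteps, by = stride) * dt * 1e3
  list(timeMs = timeMs, open = open,
       current = open * (config$vHoldMv - config$eRevMv),
       peak = max(open), occ = occ, maxLeak = out$maxLeak)
}

#' Antagonist block ratio of a simulated EPSC
#'
#' Peak open occupancy with the antagonist over the peak without; in (0, 1]
#' for a competitive antagonist.
#'
#' @inheritParams simulateEPSC
#' @return Block ratio (fraction of the control peak remaining).
#' @export
blockRatio <- function(scheme, transient, antagonistM,
                       config = epscConfig()) {
  ctl <- simulateEPSC(scheme, transient, 0, config)
  if (ctl$peak <= 0) stop("control EPSC peak is zero; block ratio undefined")
  blk <- simulateEPSC(scheme, transient, antagonistM, config)
  blk$peak / ctl$peak
}

#' Block-ratio contour over transient peak and decay
#'
#' Evaluates \code{\link{blockRatio}} on a grid of glutamate transient peak
#' concentrations and decay time constants. For a competitive antagonist the
#' surface is monotone non-decreasing along both axes (larger/longer
#' transients out-compete the antagonist).
#'
#' @param scheme,antagonistM,config as in \code{\link{blockRatio}}.
#' @param peaksM vector of transient peak concentrations (M).
#' @param tausMs vector of decay time constants (ms).
#' @return Matrix of block ratios (rows = peaks, columns = taus) with
#'   dimnames giving the axis values.
#' @export
blockContour <- function(scheme, peaksM, tausMs, antagonistM,
                         config = epscConfig()) {
  stopifnot(length(peaksM) >= 1L, length(tausMs) >= 1L)
  m <- outer(seq_along(peaksM), seq_along(tausMs),
             Vectorize(function(i, j)
               blockRatio(scheme, glutTransient(peaksM[i], tausMs[j]),
                          antagonistM, config)))
  dimnames(m) <- list(peakM = signif(peaksM, 6),
                      tauMs = signif(tausMs, 6))
  m
}

#' Extract an iso-block contour level set
#'
#' For each decay constant, interpolates the transient peak at which the
#' block ratio crosses a target level (e.g. an experimentally observed
#' block fraction).
#'
#' @param contour matrix from \code{\link{blockContour}}.
#' @param level target block ratio.
#' @return data.frame with \code{tauMs} and the interpolated \code{peakM}
#'   (NA where the level is not crossed).
#' @export
isoBlockLevel <- function(contour, level) {
  peaks <- as.numeric(rownames(contour))
  taus <- as.numeric(colnames(contour))
  peakAt <- vapply(seq_along(taus), function(j) {
    y <- contour[, j]
    if (level < min(y) || level > max(y)) return(NA_real_)
    approx(y, peaks, xout = level, ties = "ordered")$y
  }, 0)
  data.frame(tauMs = taus, peakM = peakAt)
}

#' Simulate an EPSC train
#'
#' Repeated identical glutamate transients; reports per-pulse peaks and the
#' summation index (later-pulse peak over first-pulse peak).
#'
#' @param scheme,antagonistM,config as in \code{\link{simulateEPSC}}.
#' @param transient the (first-pulse) \code{\link{glutTransient}}.
#' @param nPulses number of pulses (>= 2, default 5).
#' @param intervalMs inter-pulse interval (ms, default 100).
#' @return A list: the \code{\link{simulateEPSC}} output plus
#'   \code{pulsePeaks} and \code{summationIndex}
#'   (\code{pulsePeaks[n]/pulsePeaks[1]}).
#' @export
simulateTrain <- function(scheme, transient, nPulses = 5, intervalMs = 100,
                          antagonistM = 0, config = NULL) {
  stopifnot(nPulses >= 2)
  if (is.null(config))
    config <- epscConfig(spanMs = transient$onsetMs +
                           nPulses * intervalMs + 50)
  pulses <- lapply(seq_len(nPulses) - 1L, function(k)
    glutTransient(transient$peakM, transient$tauMs,
                  transient$onsetMs + k * intervalMs))
  res <- simulateEPSC(scheme, pulses, antagonistM, config)
  onsets <- vapply(pulses, `[[`, 0, "onsetMs")
  peaks <- vapply(seq_len(nPulses), function(k) {
    t0 <- onsets[k]
    t1 <- if (k < nPulses) onsets[k + 1L] else max(res$timeMs)
    max(res$open[res$timeMs >= t0 & res$timeMs < t1])
  }, 0)
  res$pulsePeaks <- peaks
  res$summationIndex <- peaks[nPulses] / peaks[1L]
  res
}

#' Generic AMPA-like receptor scheme with competitive antagonist binding
#'
#' An illustrative five-state scheme (unbound C, glutamate-bound CG, open O,
#' desensitized D, antagonist-bound CB) with synthetic, order-of-magnitude
#' AMPA-receptor-like rates; it is meant as an editable template (see
#' \code{\link{writeKineticScheme}}), not a fit of any published receptor
#' model.
#'
#' @param konGlu,koffGlu glutamate binding (M^-1 s^-1) and unbinding (s^-1).
#' @param beta,alpha opening and closing rates (s^-1).
#' @param kDes,kRes desensitization entry/recovery rates (s^-1); recovery is
#'   slow (~125 ms) as for AMPA receptors, so 100-ms trains desensitize.
#' @param konAnt,koffAnt antagonist binding/unbinding; the default
#'   dissociation constant (0.12 mM) mimics a low-affinity, fast competitive
#'   antagonist such as kynurenate.
#' @return A \code{KineticScheme} with conducting state \code{"O"}.
#' @export
ampaSchemeGeneric <- function(konGlu = 1e7, koffGlu = 5000, beta = 20000,
                              alpha = 8000, kDes = 1000, kRes = 8,
                              konAnt = 1e7, koffAnt = 1200) {
  kineticScheme(
    states = c("C", "CG", "O", "D", "CB"),
    transitions = data.frame(
      from = c("C", "CG", "CG", "O", "CG", "D", "C", "CB"),
      to = c("CG", "C", "O", "CG", "D", "CG", "CB", "C"),
      rate = c(konGlu, koffGlu, beta, alpha, kDes, kRes, konAnt, koffAnt),
      ligand = c("Glu", NA, NA, NA, NA, NA, "Ant", NA),
      effect = c("consume", "release", "none", "none", "none", "none",
                 "consume", "release"),
      stringsAsFactors = FALSE),
    conducting = "O")
}
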