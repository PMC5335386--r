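## Astrocyte transporter-current analysis: isolation of the facilitated STC
## (fSTC), multi-exponential kinetics, temporal centroids, derivation of the
## recording filter from sub-saturating-TBOA fSTCs and Wiener-regularized
## deconvolution to recover the glutamate clearance waveform.

#' Construct a current trace
#'
#' @param samples current samples (pA).
#' @param rateKHz sampling rate (kHz).
#' @param stimMs stimulus time (ms from record start).
#' @return A \code{\linkS4class{CurrentTrace}}.
#' @export
currentTrace <- function(samples, rateKHz = 10, stimMs = 0) {
  new("CurrentTrace", samples = as.numeric(samples), rateKHz = rateKHz,
      stimMs = stimMs)
}

#' Time base of a trace
#' @param trace a \code{CurrentTrace}.
#' @return Sample times (ms from record start).
#' @export
traceTimes <- function(trace) {
  (seq_along(trace@samples) - 1) / trace@rateKHz
}

#' Read / write a trace as two-column CSV (time ms, current pA)
#'
#' @param path CSV path.
#' @param stimMs stimulus time (ms).
#' @return \code{readTraceCSV}: a \code{CurrentTrace}.
#' @export
readTraceCSV <- function(path, stimMs = 0) {
  d <- read.csv(path)
  if (ncol(d) < 2L) stop("expected two columns: time_ms, current_pA")
  dt <- diff(d[[1L]])
  if (max(abs(dt - dt[1L])) > 1e-6) stop("non-uniform sampling in ", path)
  currentTrace(d[[2L]], rateKHz = 1 / dt[1L], stimMs = stimMs)
}

#' @rdname readTraceCSV
#' @param trace a \code{CurrentTrace}.
#' @export
writeTraceCSV <- function(trace, path) {
  write.csv(data.frame(time_ms = traceTimes(trace),
                       current_pA = trace@samples), path, row.names = FALSE)
  invisible(path)
}

baselineOf <- function(trace, baselineMs = 50) {
  i1 <- floor(trace@stimMs * trace@rateKHz)
  i0 <- max(1L, i1 - round(baselineMs * trace@rateKHz))
  if (i1 < 1L) return(0)
  mean(trace@samples[i0:i1])
}

#' Isolate the facilitated transporter current (fSTC)
#'
#' Subtracts the single-stimulus response from the paired-stimulus response,
#' re-references the residual second-pulse response to its own stimulus
#' time, and removes the single-response template again, leaving the
#' facilitated excess of the second response. A paired trace that merely
#' repeats the single response without facilitation therefore yields a zero
#' fSTC, and 1.5-fold facilitation yields an fSTC of half the single
#' amplitude.
#'
#' @param single single-stimulus \code{CurrentTrace}.
#' @param paired paired-stimulus \code{CurrentTrace} (same sampling rate and
#'   first stimulus time).
#' @param ipiMs inter-pulse interval (ms, default 100).
#' @return A \code{CurrentTrace} of the fSTC, stimulus at
#'   \code{single@stimMs}.
#' @export
isolateFSTC <- function(single, paired, ipiMs = 100) {
  if (abs(single@rateKHz - paired@rateKHz) > 1e-9)
    stop("sampling rate mismatch between single and paired traces")
  stopifnot(ipiMs > 0)
  n <- min(length(single@samples), length(paired@samples))
  d <- paired@samples[seq_len(n)] - single@samples[seq_len(n)]
  shift <- round(ipiMs * single@rateKHz)
  if (shift >= n) stop("inter-pulse interval exceeds the record")
  m <- n - shift
  out <- d[(shift + 1L):n] - single@samples[seq_len(m)]
  currentTrace(out, rateKHz = single@rateKHz, stimMs = single@stimMs)
}

#' 20-80\% rise time
#'
#' Time between the first 20\% and 80\%-of-peak crossings on the rising
#' phase, with linear interpolation between samples.
#'
#' @param trace a \code{CurrentTrace}.
#' @param baselineMs pre-stimulus baseline window (ms).
#' @return Rise time (ms).
#' @export
rise2080 <- function(trace, baselineMs = 50) {
  b <- baselineOf(trace, baselineMs)
  t <- traceTimes(trace)
  post <- t >= trace@stimMs
  y <- abs(trace@samples[post] - b)
  tt <- t[post]
  pk <- max(y)
  if (pk <= 0) stop("no identifiable peak in the trace")
  ipk <- which.max(y)
  crossing <- function(level) {
    idx <- which(y[seq_len(ipk)] >= level)[1L]
    if (is.na(idx)) stop("level never crossed on the rising phase")
    if (idx == 1L) return(tt[1L])
    frac <- (level - y[idx - 1L]) / (y[idx] - y[idx - 1L])
    tt[idx - 1L] + frac * (tt[idx] - tt[idx - 1L])
  }
  rising <- y[seq_len(ipk)]
  if (any(diff(rising) < -0.05 * pk))
    warning("non-monotonic rise; using first crossings")
  crossing(0.8 * pk) - crossing(0.2 * pk)
}

#' Temporal centroid of a trace
#'
#' First moment \code{sum(t |I|) / sum(|I|)} of the baseline-subtracted
#' current over a post-stimulus window, with time measured from the
#' stimulus.
#'
#' @param trace a \code{CurrentTrace}.
#' @param windowMs post-stimulus window (ms, default \code{c(0, 100)}).
#' @param baselineMs pre-stimulus baseline window (ms).
#' @return Centroid (ms from stimulus).
#' @export
centroidTrace <- function(trace, windowMs = c(0, 100), baselineMs = 50) {
  b <- baselineOf(trace, baselineMs)
  t <- traceTimes(trace) - trace@stimMs
  sel <- t >= windowMs[1L] & t <= windowMs[2L]
  y <- abs(trace@samples[sel] - b)
  if (sum(y) == 0) stop("zero integral in centroid window")
  sum(t[sel] * y) / sum(y)
}

#' Sustained current amplitude
#'
#' Mean baseline-subtracted current in a 50 ms window positioned 200 ms
#' after the stimulus (the sustained K+ current of astrocyte recordings).
#'
#' @param trace a \code{CurrentTrace} extending at least 250 ms past the
#'   stimulus.
#' @param baselineMs pre-stimulus baseline window (ms).
#' @return Amplitude (pA).
#' @export
measureSustainedCurrent <- function(trace, baselineMs = 50) {
  t <- traceTimes(trace) - trace@stimMs
  if (max(t) < 250) stop("record must extend >= 250 ms past the stimulus")
  b <- baselineOf(trace, baselineMs)
  sel <- t >= 200 & t <= 250
  mean(trace@samples[sel]) - b
}

## ---------------------------------------------------------------------------
## Multi-exponential fit
## ---------------------------------------------------------------------------

fstcModel <- function(t, t0, A, tauRise, tauFast, tauSlow, f, riseExp = 1) {
  out <- numeric(length(t))
  u <- t >= t0
  tt <- t[u] - t0
  out[u] <- A * (1 - exp(-tt / tauRise))^riseExp *
    (f * exp(-tt / tauFast) + (1 - f) * exp(-tt / tauSlow))
  out
}

#' Fit a rising-phase times biexponential-decay model to an fSTC
#'
#' Least-squares fit of
#' \deqn{I(t) = A (1 - e^{-(t-t_0)/\tau_{rise}})
#'   (f e^{-(t-t_0)/\tau_{fast}} + (1-f) e^{-(t-t_0)/\tau_{slow}})}
#' to the baseline-subtracted trace, with multi-start
#' Levenberg-Marquardt optimization and \code{tauFast <= tauSlow}
#' enforced by relabelling. The reported amplitude is the fitted peak
#' (pA, signed as the data); the 20-80\% rise and centroid are computed
#' from the fitted model curve.
#'
#' @param trace a \code{CurrentTrace}.
#' @param windowMs fit window relative to the stimulus (ms).
#' @param baselineMs pre-stimulus baseline window (ms).
#' @param riseExp exponent on the rising term (default 1).
#' @return A list: \code{amplitude}, \code{t0}, \code{tauRise},
#'   \code{tauFast}, \code{tauSlow}, \code{fFast}, \code{rise2080},
#'   \code{centroid}, \code{rss}, \code{r2}, \code{converged}.
#' @export
fitMultiExponential <- function(trace, windowMs = c(-2, 150),
                                baselineMs = 50, riseExp = 1) {
  b <- baselineOf(trace, baselineMs)
  t <- traceTimes(trace) - trace@stimMs
  sel <- t >= windowMs[1L] & t <= windowMs[2L]
  tt <- t[sel]
  yraw <- trace@samples[sel] - b
  sgn <- if (abs(min(yraw)) > abs(max(yraw))) -1 else 1
  y <- sgn * yraw
  pk <- max(y); ipk <- which.max(y)
  if (pk <= 0) stop("no response in the fit window")
  ## crude scales for starts
  tPk <- tt[ipk]
  after <- y[ipk:length(y)]
  t50 <- tt[ipk - 1L + which(after <= pk / 2)[1L]]
  tDecay <- if (is.na(t50)) diff(range(tt)) / 4 else (t50 - tPk) / log(2)
  tDecay <- max(tDecay, 0.5)
  best <- NULL
  for (rRise in c(0.3, 1, 3)) for (rF in c(0.5, 1)) for (f0 in c(0.3, 0.6,
                                                                 0.9)) {
    st <- list(A = pk * 1.5, t0 = max(tt[1L], 0), tauRise = rRise,
               tauFast = tDecay * rF, tauSlow = tDecay * 3.5, f = f0)
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ fstcModel(tt, t0, A, tauRise, tauFast, tauSlow, f, riseExp),
      start = st,
      lower = c(A = 0, t0 = windowMs[1L], tauRise = 0.01, tauFast = 0.05,
                tauSlow = 0.05, f = 0),
      upper = c(A = Inf, t0 = tPk, tauRise = 50, tauFast = 500,
                tauSlow = 1000, f = 1),
      control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    ## degenerate decays (e.g. a pure single exponential) can make the full
    ## model's Jacobian singular: fall back to f pinned at 1
    for (rRise in c(0.3, 1, 3)) {
      st <- list(A = pk * 1.5, t0 = max(tt[1L], 0), tauRise = rRise,
                 tauFast = tDecay)
      fit <- tryCatch(minpack.lm::nlsLM(
        y ~ fstcModel(tt, t0, A, tauRise, tauFast, tauFast, 1, riseExp),
        start = st,
        lower = c(A = 0, t0 = windowMs[1L], tauRise = 0.01, tauFast = 0.05),
        upper = c(A = Inf, t0 = tPk, tauRise = 50, tauFast = 1000),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
      stop("multi-exponential fit failed to converge from any start")
    cf <- as.list(coef(best$fit))
    best$fit <- NULL
    best$pinned <- c(cf, list(tauSlow = cf$tauFast, f = 1))
  }
  p <- if (is.null(best$fit)) best$pinned else as.list(coef(best$fit))
  if (p$tauFast > p$tauSlow) {   # relabel so tauFast <= tauSlow
    tmp <- p$tauFast; p$tauFast <- p$tauSlow; p$tauSlow <- tmp
    p$f <- 1 - p$f
  }
  ## model-derived summaries on a fine grid
  tg <- seq(p$t0, max(tt), by = 0.01)
  yg <- fstcModel(tg, p$t0, p$A, p$tauRise, p$tauFast, p$tauSlow, p$f,
                  riseExp)
  pkM <- max(yg); ipkM <- which.max(yg)
  cross <- function(level) {
    i <- which(yg[seq_len(ipkM)] >= level)[1L]
    if (i <= 1L) return(tg[1L])
    tg[i - 1L] + (level - yg[i - 1L]) / (yg[i] - yg[i - 1L]) * 0.01
  }
  r28 <- cross(0.8 * pkM) - cross(0.2 * pkM)
  cen <- sum((tg - p$t0) * yg) / sum(yg)
  tot <- sum((y - mean(y))^2)
  list(amplitude = sgn * pkM, t0 = p$t0, tauRise = p$tauRise,
       tauFast = p$tauFast, tauSlow = p$tauSlow, fFast = p$f,
       rise2080 = r28, centroid = cen, rss = best$rss,
       r2 = 1 - best$rss / tot,
       converged = if (is.null(best$fit)) TRUE
                   else isTRUE(best$fit$convInfo$isConv))
}

## ---------------------------------------------------------------------------
## Deconvolution
## ---------------------------------------------------------------------------

## zero-padded FFT deconvolution with scalar Wiener regularization
wienerDeconvolve <- function(x, h, nsrRel) {
  N <- 2^ceiling(log2(length(x) + length(h)))
  X <- fft(c(x, rep(0, N - length(x))))
  H <- fft(c(h, rep(0, N - length(h))))
  P <- Mod(H)^2
  G <- Conj(H) / (P + nsrRel * max(P))
  Re(fft(X * G, inverse = TRUE))[seq_along(x)] / N
}

## discrete causal convolution, trimmed to length(x)
convolveCausal <- function(x, h) {
  n <- length(x)
  y <- convolve(c(x, rep(0, length(h))), rev(c(h, rep(0, n))),
                type = "open")
  y[seq_len(n)]
}

estimateNSR <- function(trace, baselineMs = 50) {
  i1 <- floor(trace@stimMs * trace@rateKHz)
  i0 <- max(1L, i1 - round(baselineMs * trace@rateKHz))
  y <- trace@samples - mean(trace@samples[i0:max(i1, i0 + 1L)])
  nv <- if (i1 > i0 + 4L) var(y[i0:i1]) else 0
  sp <- mean(y^2)
  if (sp <= 0) return(1e-6)
  min(max(nv / sp, 1e-8), 0.5)
}

#' Derive the recording filter from a sub-saturating-TBOA fSTC
#'
#' With most transporters blocked the fSTC decay approximates the glutamate
#' clearance time course, so clearance is modelled as an instantaneously
#' rising waveform (onset at the stimulus) decaying with the biexponential
#' fitted to the post-peak decay of the input; the filter is recovered by
#' deconvolving that waveform from the recorded trace and normalized to
#' unit area. Fitting only the decay phase keeps the clearance model free
#' of the rise-time distortion that the filter itself produces.
#'
#' @param fstcTboa fSTC recorded in sub-saturating TBOA
#'   (a \code{CurrentTrace}).
#' @param nsrRel Wiener regularization (relative noise-to-signal); estimated
#'   from the pre-stimulus segment when \code{NULL}.
#' @param windowMs decay-fit window (ms from stimulus); the fit runs from
#'   the trace peak to the window end.
#' @return Numeric filter vector (unit sum) with attributes \code{"dtMs"}
#'   and \code{"fit"} (the decay-fit parameters).
#' @export
deriveFilter <- function(fstcTboa, nsrRel = NULL, windowMs = c(-2, 200)) {
  dt <- 1 / fstcTboa@rateKHz
  b <- baselineOf(fstcTboa)
  t <- traceTimes(fstcTboa) - fstcTboa@stimMs
  y <- abs(fstcTboa@samples - b)
  inWin <- t <= windowMs[2L]
  ipk <- which.max(y * inWin)
  sel <- which(t >= t[ipk] & inWin)
  tt <- t[sel]; yd <- y[sel]
  pk <- y[ipk]
  best <- NULL
  for (rf in c(0.5, 1, 2)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      yd ~ a1 * exp(-tt / tf) + a2 * exp(-tt / ts),
      start = list(a1 = pk * 0.6, a2 = pk * 0.3, tf = 8 * rf, ts = 40 * rf),
      lower = c(a1 = 0, a2 = 0, tf = 0.1, ts = 0.1),
      control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("biexponential decay fit failed")
  p <- as.list(coef(best$fit))
  if (p$tf > p$ts) p <- list(a1 = p$a2, a2 = p$a1, tf = p$ts, ts = p$tf)
  clr <- ifelse(t >= 0, p$a1 * exp(-t / p$tf) + p$a2 * exp(-t / p$ts), 0)
  if (max(clr) <= 0) stop("degenerate decay fit")
  clr <- clr / max(clr)
  if (is.null(nsrRel)) nsrRel <- estimateNSR(fstcTboa)
  h <- wienerDeconvolve(y, clr, nsrRel)
  h[h < 0] <- 0
  if (sum(h) <= 0) stop("degenerate filter (all-zero)")
  h <- h / sum(h)
  attr(h, "dtMs") <- dt
  attr(h, "fit") <- list(tauFast = p$tf, tauSlow = p$ts,
                         fFast = p$a1 / (p$a1 + p$a2), rss = best$rss)
  h
}

#' Estimate the glutamate clearance waveform by deconvolution
#'
#' Wiener-regularized frequency-domain deconvolution of the control fSTC by
#' the filter derived in sub-saturating TBOA. The estimate is rectified:
#' values below a small fraction of the peak (negative excursions and
#' residual broadband noise) are set to zero before the centroid is
#' computed.
#'
#' @param fstcCtrl control fSTC (a \code{CurrentTrace}).
#' @param filter filter vector (unit sum) from \code{\link{deriveFilter}} or
#'   a synthetic kernel.
#' @param nsrRel Wiener regularization; estimated from the pre-stimulus
#'   segment when \code{NULL}.
#' @param windowMs centroid window (ms from stimulus).
#' @param rectify rectification threshold as a fraction of the clearance
#'   peak; values below it are zeroed (default 0: only negative excursions
#'   are rectified, preserving genuine slow-tail mass).
#' @return A list: \code{clearance} (normalized waveform on the input time
#'   base), \code{centroid} (ms), \code{timeMs}, \code{filter},
#'   \code{nsrRel}.
#' @export
estimateClearance <- function(fstcCtrl, filter, nsrRel = NULL,
                              windowMs = c(0, 100), rectify = 0) {
  if (sum(filter) <= 0) stop("filter must have positive area")
  filter <- filter / sum(filter)
  if (is.null(nsrRel)) nsrRel <- estimateNSR(fstcCtrl)
  b <- baselineOf(fstcCtrl)
  y <- abs(fstcCtrl@samples - b)
  cl <- wienerDeconvolve(y, filter, nsrRel)
  cl[cl < rectify * max(cl)] <- 0
  t <- traceTimes(fstcCtrl) - fstcCtrl@stimMs
  sel <- t >= windowMs[1L] & t <= windowMs[2L]
  if (sum(cl[sel]) == 0) stop("deconvolved clearance is identically zero")
  cen <- sum(t[sel] * cl[sel]) / sum(cl[sel])
  if (max(cl) > 0) cl <- cl / max(cl)
  list(clearance = cl, centroid = cen, timeMs = t, filter = filter,
       nsrRel = nsrRel)
}

#' Fit-based clearance estimation (deconvolution alternative)
#'
#' Parameterizes clearance as an instantaneously rising biexponential and
#' optimizes its parameters so that clearance convolved with the filter
#' reproduces the recorded fSTC; an independent route to
#' \code{\link{estimateClearance}} that avoids frequency-domain division
#' entirely (useful as a cross-check, and more robust when the noise floor
#' is hard to estimate).
#'
#' @inheritParams estimateClearance
#' @return A list as in \code{\link{estimateClearance}}, plus \code{params}
#'   (the fitted biexponential: \code{tauFast}, \code{tauSlow},
#'   \code{fFast}).
#' @export
estimateClearanceFit <- function(fstcCtrl, filter, windowMs = c(0, 100)) {
  if (sum(filter) <= 0) stop("filter must have positive area")
  filter <- filter / sum(filter)
  b <- baselineOf(fstcCtrl)
  t <- traceTimes(fstcCtrl) - fstcCtrl@stimMs
  y <- abs(fstcCtrl@samples - b)
  model <- function(A, tf, ts, f) {
    clr <- ifelse(t >= 0, f * exp(-t / tf) + (1 - f) * exp(-t / ts), 0)
    A * convolveCausal(clr, filter)
  }
  pk <- max(y)
  best <- NULL
  for (tf0 in c(3, 6, 12)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ model(A, tf, ts, f),
      start = list(A = pk, tf = tf0, ts = tf0 * 4, f = 0.6),
      lower = c(A = 0, tf = 0.1, ts = 0.1, f = 0),
      upper = c(A = Inf, tf = 500, ts = 1000, f = 1),
      control = nls.control(maxiter = 100, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("fit-based clearance estimation failed")
  p <- as.list(coef(best$fit))
  if (p$tf > p$ts) {
    tmp <- p$tf; p$tf <- p$ts; p$ts <- tmp; p$f <- 1 - p$f
  }
  clr <- ifelse(t >= 0, p$f * exp(-t / p$tf) + (1 - p$f) * exp(-t / p$ts),
                0)
  sel <- t >= windowMs[1L] & t <= windowMs[2L]
  cen <- sum(t[sel] * clr[sel]) / sum(clr[sel])
  list(clearance = clr / max(clr), centroid = cen, timeMs = t,
       filter = filter, nsrRel = NA_real_,
       params = list(tauFast = p$tf, tauSlow = p$ts, fFast = p$f,
                     amplitude = p$A))
}
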