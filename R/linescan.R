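## Two-photon line-scan diffusion analysis: Gaussian profile fits with
## pre-puff subtraction, gamma^2/4-versus-time regression for the diffusion
## coefficient, tortuosity and Stokes-Einstein hydrodynamic diameter.

BOLTZMANN <- 1.380649e-23   # J/K

#' Construct a kymograph
#'
#' @param intensity matrix, position (rows) x time (columns).
#' @param pixelUm pixel size along the scan line (um).
#' @param lineRateHz line rate (Hz).
#' @param puffLine column index of the pressure application.
#' @return A \code{\linkS4class{Kymograph}}.
#' @export
kymograph <- function(intensity, pixelUm, lineRateHz = 625, puffLine) {
  new("Kymograph", intensity = as.matrix(intensity), pixelUm = pixelUm,
      lineRateHz = lineRateHz, puffLine = puffLine)
}

#' Read / write a kymograph as CSV plus JSON sidecar
#'
#' The CSV holds the intensity matrix (rows = pixels); the sidecar holds
#' \code{pixelUm}, \code{lineRateHz} and \code{puffLine}.
#'
#' @param path CSV path; the sidecar is \code{paste0(path, ".json")}.
#' @return \code{readKymographCSV}: a \code{Kymograph}.
#' @export
readKymographCSV <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  kymograph(m, pixelUm = meta$pixelUm, lineRateHz = meta$lineRateHz,
            puffLine = meta$puffLine)
}

#' @rdname readKymographCSV
#' @param kymo a \code{Kymograph}.
#' @export
writeKymographCSV <- function(kymo, path) {
  write.table(kymo@intensity, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(pixelUm = kymo@pixelUm,
                            lineRateHz = kymo@lineRateHz,
                            puffLine = kymo@puffLine),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Extract baseline-subtracted fluorescence profiles
#'
#' Samples intensity profiles every \code{intervalMs} after the puff and
#' subtracts the average pre-puff profile (removing residual fluorescence
#' from earlier applications).
#'
#' @param kymo a \code{Kymograph}.
#' @param intervalMs sampling cadence (ms, default 150).
#' @return A list: \code{x} (positions, um), \code{timeS} (times since puff,
#'   s), \code{profiles} (matrix, position x profile).
#' @export
extractProfiles <- function(kymo, intervalMs = 150) {
  if (kymo@puffLine < 2) stop("no pre-puff lines: cannot form a baseline")
  step <- round(intervalMs * kymo@lineRateHz / 1000)
  idx <- seq(kymo@puffLine + step, ncol(kymo@intensity), by = step)
  if (!length(idx)) stop("record too short for the profile cadence")
  base <- rowMeans(kymo@intensity[, seq_len(kymo@puffLine - 1L),
                                  drop = FALSE])
  prof <- kymo@intensity[, idx, drop = FALSE] - base
  list(x = (seq_len(nrow(kymo@intensity)) - 1) * kymo@pixelUm,
       timeS = (idx - kymo@puffLine) / kymo@lineRateHz,
       profiles = prof)
}

#' Fit a Gaussian to a fluorescence profile
#'
#' Levenberg-Marquardt least squares of
#' \code{A exp(-(x - x0)^2 / gamma^2) + c}; the width convention matches
#' the diffusion relation \code{gamma^2 = 4 D t} for a spreading point
#' source.
#'
#' @param x positions (um).
#' @param y intensities.
#' @param fitOffset fit a free additive offset; disable for profiles that
#'   are already baseline-subtracted (removes the offset/width degeneracy
#'   when the Gaussian wings exceed the scanned field).
#' @return A list: \code{A}, \code{x0}, \code{gamma}, \code{offset},
#'   \code{gammaSE}, \code{converged}.
#' @export
fitGaussianProfile <- function(x, y, fitOffset = TRUE) {
  if (length(x) < 10L) stop("profile needs at least 10 samples")
  off0 <- min(y)
  a0 <- max(y) - off0
  if (a0 <= 0 || sd(y) < 1e-12)
    return(list(A = NA, x0 = NA, gamma = NA, offset = off0, gammaSE = NA,
                converged = FALSE))
  w <- pmax(y - off0, 0)
  x00 <- sum(x * w) / sum(w)
  g0 <- sqrt(2 * sum((x - x00)^2 * w) / sum(w))
  g0 <- max(g0, diff(range(x)) / 50)
  fit <- tryCatch(
    if (fitOffset) minpack.lm::nlsLM(
      y ~ A * exp(-(x - x0)^2 / gamma^2) + c0,
      start = list(A = a0, x0 = x00, gamma = g0, c0 = off0),
      lower = c(A = 0, x0 = min(x), gamma = 1e-6, c0 = -Inf),
      control = nls.control(maxiter = 100, warnOnly = TRUE))
    else minpack.lm::nlsLM(
      y ~ A * exp(-(x - x0)^2 / gamma^2),
      start = list(A = a0, x0 = x00, gamma = g0),
      lower = c(A = 0, x0 = min(x), gamma = 1e-6),
      control = nls.control(maxiter = 100, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$convInfo$isConv)
    return(list(A = NA, x0 = NA, gamma = NA, offset = NA, gammaSE = NA,
                converged = FALSE))
  p <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["gamma", "Std. Error"],
                 error = function(e) NA)
  list(A = unname(p["A"]), x0 = unname(p["x0"]),
       gamma = unname(abs(p["gamma"])),
       offset = if (fitOffset) unname(p["c0"]) else 0,
       gammaSE = se, converged = TRUE)
}

#' Estimate a diffusion coefficient from profile widths
#'
#' Linear regression of \code{gamma^2 / 4} against time since the puff over
#' a fixed window (default 2 s), in which the spread of a point source is
#' linear in time; the slope is the (free or apparent) diffusion
#' coefficient.
#'
#' @param fits data.frame with columns \code{timeS} and \code{gamma} (um),
#'   e.g. assembled from \code{\link{fitGaussianProfile}} results.
#' @param windowS regression window after the puff (s).
#' @return A list: \code{D} (um^2/ms), \code{r2}, \code{nProfiles},
#'   \code{fit} (the lm object).
#' @export
estimateDiffusionCoefficient <- function(fits, windowS = 2) {
  ok <- is.finite(fits$gamma) & fits$timeS <= windowS
  if (sum(ok) < 3L) stop("need at least 3 usable profiles in the window")
  tMs <- fits$timeS[ok] * 1000
  q <- fits$gamma[ok]^2 / 4
  fit <- lm(q ~ tMs)
  D <- unname(coef(fit)[2L])
  if (D < 0) warning("negative regression slope; reporting D as fitted")
  tot <- sum((q - mean(q))^2)
  r2 <- if (tot > 0) 1 - sum(residuals(fit)^2) / tot else 1
  list(D = D, r2 = r2, nProfiles = sum(ok), fit = fit)
}

#' Tortuosity from free and apparent diffusion coefficients
#'
#' \code{lambda = sqrt(dFree / dStar)}: the hindrance to diffusion
#' experienced in tissue relative to free solution.
#'
#' @param dFree free-solution diffusion coefficient (um^2/ms).
#' @param dStar apparent coefficient in tissue (um^2/ms).
#' @return Tortuosity (dimensionless); values < 1 trigger a warning.
#' @export
tortuosity <- function(dFree, dStar) {
  stopifnot(dFree > 0, dStar > 0)
  l <- sqrt(dFree / dStar)
  if (l < 1) warning("tortuosity < 1: apparent D exceeds free D")
  l
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' \code{d_H = K T / (3 pi eta D)} with K Boltzmann's constant. The
#' coefficient passed is used as-is (conventionally the free-solution D;
#' applying it to the apparent in-tissue coefficient reproduces the
#' slice-based estimates).
#'
#' @param d diffusion coefficient (um^2/ms).
#' @param temperatureK temperature (K, default 295).
#' @param etaPaS solvent viscosity (Pa s, default 9.68e-4, water at 295 K).
#' @return Diameter (nm).
#' @export
hydrodynamicDiameter <- function(d, temperatureK = 295, etaPaS = 9.68e-4) {
  stopifnot(d > 0)
  dSI <- d * 1e-9                       # um^2/ms -> m^2/s
  BOLTZMANN * temperatureK / (3 * pi * etaPaS * dSI) * 1e9
}

#' End-to-end kymograph diffusion analysis
#'
#' Extracts profiles, fits Gaussians (dropping failed fits) and regresses
#' \code{gamma^2/4} on time.
#'
#' @param kymo a \code{Kymograph}.
#' @param intervalMs profile cadence (ms).
#' @param windowS regression window (s).
#' @return As \code{\link{estimateDiffusionCoefficient}}, plus
#'   \code{profileFits} (data.frame of per-profile Gaussian fits).
#' @export
analyzeKymograph <- function(kymo, intervalMs = 150, windowS = 2) {
  pr <- extractProfiles(kymo, intervalMs)
  fits <- do.call(rbind, lapply(seq_len(ncol(pr$profiles)), function(j) {
    g <- fitGaussianProfile(pr$x, pr$profiles[, j], fitOffset = FALSE)
    data.frame(timeS = pr$timeS[j], gamma = g$gamma, A = g$A,
               converged = g$converged)
  }))
  est <- estimateDiffusionCoefficient(fits, windowS)
  est$profileFits <- fits
  est
}

#' @describeIn Kymograph-class compact display
#' @param object a \code{Kymograph}
#' @export
setMethod("show", "Kymograph", function(object) {
  cat(sprintf(
    "Kymograph: %d px x %d lines, %.3g um/px, %g Hz, puff at line %d\n",
    nrow(object@intensity), ncol(object@intensity), object@pixelUm,
    object@lineRateHz, as.integer(object@puffLine)))
})
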