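## Ligand-driven Markov schemes: the simplified astrocytic glutamate
## transporter cycle, temperature (Q10) scaling, YAML scheme interchange and
## a deterministic well-mixed propagator used as a calibration oracle.

#' Q10 temperature scaling of a kinetic rate
#'
#' @param rate rate constant (s^-1 or M^-1 s^-1).
#' @param q10 fold change per 10 degrees C.
#' @param tRef reference temperature (degrees C).
#' @param tTarget target temperature (degrees C).
#' @return \code{rate * q10^((tTarget - tRef)/10)}.
#' @export
q10Scale <- function(rate, q10, tRef, tTarget) {
  stopifnot(q10 > 0)
  rate * q10^((tTarget - tRef) / 10)
}

#' Transporter kinetic parameters
#'
#' Defaults are the simplified astrocytic transporter cycle: binding
#' \code{kOn} = 6e6 M^-1 s^-1, unbinding \code{kOff} = 601 s^-1,
#' translocation \code{kTrans} = 2,000 s^-1 and reorientation
#' \code{kReorient} = 50 s^-1, with an independently stated apparent
#' steady-state affinity \code{km} = 13 uM and Q10 = 3 scaling from 25 to
#' 35 degrees C. \code{km} and \code{kOff} are kept as independent entries:
#' the printed pair is not mutually consistent under the cyclic steady-state
#' affinity of this scheme (see \code{\link{apparentKm}}).
#'
#' @param kOn,kOff,kTrans,kReorient rate constants (see above).
#' @param km apparent steady-state affinity (M), metadata.
#' @param q10 fold rate change per 10 degrees C.
#' @param tRef,tSim reference and simulation temperatures (degrees C).
#' @return A named list of parameters.
#' @export
transporterParams <- function(kOn = 6e6, kOff = 601, kTrans = 2000,
                              kReorient = 50, km = 13e-6, q10 = 3,
                              tRef = 25, tSim = 35) {
  stopifnot(kOn > 0, kOff > 0, kTrans >= 0, kReorient > 0, q10 >= 1)
  list(kOn = kOn, kOff = kOff, kTrans = kTrans, kReorient = kReorient,
       km = km, q10 = q10, tRef = tRef, tSim = tSim)
}

#' Construct a kinetic scheme
#'
#' @param states character state names.
#' @param transitions data.frame with columns \code{from}, \code{to},
#'   \code{rate}, \code{ligand} (NA for unimolecular transitions) and
#'   \code{effect} (\code{"none"}, \code{"consume"}, \code{"release"},
#'   \code{"sequester"}).
#' @param conducting conducting state names.
#' @return A \code{\linkS4class{KineticScheme}}.
#' @export
kineticScheme <- function(states, transitions, conducting = character(0)) {
  transitions$from <- as.character(transitions$from)
  transitions$to <- as.character(transitions$to)
  transitions$ligand <- as.character(transitions$ligand)
  if (!"effect" %in% names(transitions)) {
    transitions$effect <- ifelse(is.na(transitions$ligand), "none", "consume")
  }
  new("KineticScheme", states = states, transitions = transitions,
      conducting = conducting)
}

#' Build the simplified glutamate transporter scheme
#'
#' Three states: outward-facing free (\code{T}), outward-facing bound
#' (\code{TG}) and inward-facing (\code{Tin}). Transitions:
#' \code{T + Glu -> TG} (\code{kOn}, consumes a free glutamate),
#' \code{TG -> T} (\code{kOff}, releases it), \code{TG -> Tin}
#' (\code{kTrans}, glutamate permanently sequestered) and \code{Tin -> T}
#' (\code{kReorient}). With \code{applyQ10 = TRUE} every rate (including the
#' bimolecular binding rate) is scaled by
#' \code{q10^((tSim - tRef)/10)}.
#'
#' @param params a list from \code{\link{transporterParams}}.
#' @param applyQ10 scale rates to the simulation temperature.
#' @return A \code{KineticScheme}.
#' @export
transporterScheme <- function(params = transporterParams(), applyQ10 = FALSE) {
  f <- if (applyQ10) q10Scale(1, params$q10, params$tRef, params$tSim) else 1
  tr <- data.frame(
    from = c("T", "TG", "TG", "Tin"),
    to = c("TG", "T", "Tin", "T"),
    rate = f * c(params$kOn, params$kOff, params$kTrans, params$kReorient),
    ligand = c("Glu", NA, NA, NA),
    effect = c("consume", "release", "sequester", "none"),
    stringsAsFactors = FALSE)
  if (params$kTrans == 0) tr <- tr[tr$rate > 0 | tr$from == "Tin", ]
  kineticScheme(c("T", "TG", "Tin"), tr)
}

#' Apparent steady-state affinity of the transporter cycle
#'
#' Glutamate concentration at which the steady-state translocation flux of
#' the three-state cycle is half its saturating value:
#' \deqn{K_m = \frac{(k_{off} + k_{trans})\,k_{reorient}}
#'                  {k_{on}\,(k_{reorient} + k_{trans})}}
#' As \code{kTrans -> 0} this reduces to the equilibrium dissociation
#' constant \code{kOff/kOn}.
#'
#' @param params a list from \code{\link{transporterParams}}.
#' @return Affinity in M.
#' @export
apparentKm <- function(params = transporterParams()) {
  den <- params$kOn * (params$kReorient + params$kTrans)
  if (den == 0) stop("zero denominator in apparent Km")
  (params$kOff + params$kTrans) * params$kReorient / den
}

## ---------------------------------------------------------------------------
## Scheme YAML interchange
## ---------------------------------------------------------------------------

#' Read / write a kinetic scheme as YAML
#'
#' The file holds \code{states}, \code{transitions} (each with \code{from},
#' \code{to}, \code{rate}, optional \code{ligand} and \code{effect}) and an
#' optional \code{conducting} list. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return \code{readKineticScheme}: a \code{KineticScheme}.
#' @export
readKineticScheme <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), c("states", "transitions", "conducting"))
  if (length(bad)) stop("unknown scheme key(s): ", paste(bad, collapse = ", "))
  if (is.null(vals$states) || is.null(vals$transitions))
    stop("scheme file must declare states and transitions")
  tr <- do.call(rbind, lapply(vals$transitions, function(t) {
    bad <- setdiff(names(t), c("from", "to", "rate", "ligand", "effect"))
    if (length(bad)) stop("unknown transition key(s): ",
                          paste(bad, collapse = ", "))
    data.frame(from = t$from, to = t$to, rate = as.numeric(t$rate),
               ligand = if (is.null(t$ligand)) NA_character_ else t$ligand,
               effect = if (is.null(t$effect)) NA_character_ else t$effect,
               stringsAsFactors = FALSE)
  }))
  tr$effect <- ifelse(is.na(tr$effect),
                      ifelse(is.na(tr$ligand), "none", "consume"), tr$effect)
  kineticScheme(unlist(vals$states), tr,
                conducting = as.character(unlist(vals$conducting)))
}

#' @rdname readKineticScheme
#' @param scheme a \code{KineticScheme}.
#' @export
writeKineticScheme <- function(scheme, path) {
  tr <- scheme@transitions
  trl <- lapply(seq_len(nrow(tr)), function(i) {
    x <- list(from = tr$from[i], to = tr$to[i], rate = tr$rate[i])
    if (!is.na(tr$ligand[i])) x$ligand <- tr$ligand[i]
    x$effect <- tr$effect[i]
    x
  })
  yaml::write_yaml(list(states = as.list(scheme@states), transitions = trl,
                        conducting = as.list(scheme@conducting)), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Well-mixed deterministic propagation
## ---------------------------------------------------------------------------

## generator matrix Q (rates i->j) at ligand concentration L (M); named
## ligand concentrations in `ligands` override L for matching transitions
schemeGenerator <- function(scheme, L, ligands = NULL) {
  n <- length(scheme@states)
  Q <- matrix(0, n, n, dimnames = list(scheme@states, scheme@states))
  tr <- scheme@transitions
  for (i in seq_len(nrow(tr))) {
    conc <- 1
    if (!is.na(tr$ligand[i])) {
      conc <- if (!is.null(ligands) && tr$ligand[i] %in% names(ligands))
        ligands[[tr$ligand[i]]] else L
    }
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + tr$rate[i] * conc
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Deterministic well-mixed propagation of a kinetic scheme
#'
#' Integrates the master equation \code{dp/dt = p Q(L(t))} with fixed-step
#' RK4 under a prescribed ligand concentration time course. Occupancies stay
#' a probability vector at every step; for constant ligand the result matches
#' the matrix-exponential solution.
#'
#' @param scheme a \code{KineticScheme}.
#' @param ligand numeric vector of ligand concentration (M) at each step, or
#'   a single value held constant.
#' @param dt step size (s).
#' @param nSteps number of steps (defaults to \code{length(ligand) - 1}).
#' @param p0 initial occupancy vector (defaults to all mass in state 1).
#' @return Matrix (nSteps + 1) x nStates of occupancies, with the time base
#'   (s) as attribute \code{"time"}.
#' @export
integrateWellMixed <- function(scheme, ligand, dt, nSteps = NULL, p0 = NULL) {
  n <- length(scheme@states)
  if (is.null(nSteps)) nSteps <- max(length(ligand) - 1L, 1L)
  if (length(ligand) == 1L) ligand <- rep(ligand, nSteps + 1L)
  if (length(ligand) < nSteps + 1L) stop("ligand time course too short")
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1L))
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop("p0 must be a probability vector")
  maxRate <- max(abs(diag(schemeGenerator(scheme, max(ligand)))))
  if (maxRate * dt > 2)
    stop("dt too large for stable integration (max rate ", signif(maxRate, 3),
         " /s); reduce dt below ", signif(2 / maxRate, 3), " s")
  out <- matrix(NA_real_, nSteps + 1L, n,
                dimnames = list(NULL, scheme@states))
  out[1L, ] <- p0
  p <- p0
  for (k in seq_len(nSteps)) {
    L0 <- ligand[k]; L1 <- ligand[k + 1L]; Lm <- (L0 + L1) / 2
    Q0 <- schemeGenerator(scheme, L0)
    Qm <- schemeGenerator(scheme, Lm)
    Q1 <- schemeGenerator(scheme, L1)
    k1 <- p %*% Q0
    k2 <- (p + dt / 2 * k1) %*% Qm
    k3 <- (p + dt / 2 * k2) %*% Qm
    k4 <- (p + dt * k3) %*% Q1
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p <- as.numeric(p)
    if (abs(sum(p) - 1) > 1e-9)
      stop("occupancy conservation lost at step ", k)
    out[k + 1L, ] <- p
  }
  attr(out, "time") <- dt * (0:nSteps)
  out
}

#' Steady-state cycle flux of the transporter scheme
#'
#' Translocation flux (per transporter, s^-1) of the three-state cycle at a
#' constant glutamate concentration, from the analytic steady state.
#'
#' @param params a list from \code{\link{transporterParams}}.
#' @param glu glutamate concentration (M); may be a vector.
#' @return Flux values (s^-1).
#' @export
transporterCycleFlux <- function(params, glu) {
  vapply(glu, function(L) {
    kb <- params$kOn * L
    ## solve pi Q = 0 for the 3-state chain T -> TG -> Tin -> T
    A <- rbind(c(-kb, params$kOff, params$kReorient),
               c(kb, -(params$kOff + params$kTrans), 0),
               c(1, 1, 1))
    p <- solve(A, c(0, 0, 1))
    params$kTrans * p[2L]
  }, 0)
}

#' @describeIn KineticScheme-class compact display
#' @param object a \code{KineticScheme}
#' @export
setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme: %d states (%s)\n", length(object@states),
              paste(object@states, collapse = ", ")))
  tr <- object@transitions
  for (i in seq_len(nrow(tr))) {
    lig <- if (is.na(tr$ligand[i])) "" else paste0(" + ", tr$ligand[i])
    cat(sprintf("  %s%s -> %s  rate %g%s  [%s]\n", tr$from[i], lig, tr$to[i],
                tr$rate[i], if (is.na(tr$ligand[i])) " /s" else " /M/s",
                tr$effect[i]))
  }
  if (length(object@conducting))
    cat("  conducting:", paste(object@conducting, collapse = ", "), "\n")
})
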