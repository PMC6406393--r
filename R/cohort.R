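#' Compute the no-treatment limit cycle
#'
#' Integrates the circuit without treatment past a burn-in, detects the
#' oscillation, and returns one densely sampled cycle (between the last two
#' peaks of HIPK1-PAGE4) together with its period, its centroid in the
#' (H, C) plane, and the per-species midrange thresholds
#' (mean of cycle minimum and maximum) used for phenotype classification.
#'
#' @param params a [CircuitParams-class] object.
#' @param burnIn transient to discard (h).
#' @param tEnd total integration time (h).
#' @param outputDt sampling step of the returned cycle (h).
#' @return list with elements \code{times} (phase times in \code{[0,
#'   period)}), \code{states} (matrix, one row per time), \code{period},
#'   \code{center} (named \code{c(H, C)}) and \code{mid} (named
#'   \code{c(h_mid, c_mid)}).
#' @export
limitCycle <- function(params, burnIn = 3000, tEnd = 5000, outputDt = 0.2) {
  traj <- simulateCircuit(params, noTreatment(), .canonicalInit(),
                          c(0, tEnd), outputDt)
  osc <- detectPeriod(traj, "H", burnIn)
  if (!osc@isOscillating)
    stop("no limit cycle: the dynamics settle to a fixed point for these ",
         "parameters")
  pk <- osc@peakTimes
  t0 <- pk[length(pk) - 1L]
  t1 <- pk[length(pk)]
  sel <- traj@times >= t0 & traj@times < t1
  states <- traj@states[sel, , drop = FALSE]
  mid <- function(x) (min(x) + max(x)) / 2
  list(times = traj@times[sel] - t0,
       states = states,
       period = t1 - t0,
       center = c(H = mean(states[, "H"]), C = mean(states[, "C"])),
       mid = c(h_mid = mid(states[, "H"]), c_mid = mid(states[, "C"])))
}

# linear interpolation of the cycle at absolute phase-time tau in [0, period)
.cycleStateAt <- function(cycle, tau) {
  tt <- c(cycle$times, cycle$period)
  st <- rbind(cycle$states, cycle$states[1L, ])
  vapply(.species, function(sp)
    stats::approx(tt, st[, sp], xout = tau)$y, numeric(length(tau)))
}

#' Sample unsynchronized initial conditions on the limit cycle
#'
#' Draws \code{nCells} phases uniformly on \code{[0, 1)} of the no-treatment
#' limit-cycle period and returns the cycle states at those phases. This is
#' the package's model of an unsynchronized cohort: cells are identical in
#' parameters and differ only in oscillation phase. Deterministic given
#' \code{seed}.
#'
#' @param params a [CircuitParams-class] object with a limit cycle (an error
#'   is raised for fixed-point-only dynamics).
#' @param nCells number of cells (>= 1).
#' @param seed integer RNG seed (default 42).
#' @param cycle optional precomputed [limitCycle()] result.
#' @return numeric matrix \code{nCells x 5} (columns \code{W,H,C,K,A}), one
#'   initial state per row, with the sampled phases (fractions of the
#'   period) in \code{attr(, "phases")}.
#' @export
sampleInitialConditions <- function(params, nCells, seed = 42L,
                                    cycle = NULL) {
  if (nCells < 1L) stop("'nCells' must be >= 1")
  if (is.null(cycle)) cycle <- limitCycle(params)
  phases <- withr::with_seed(as.integer(seed), stats::runif(nCells))
  states <- .cycleStateAt(cycle, phases * cycle$period)
  states <- matrix(states, nrow = nCells, ncol = 5L,
                   dimnames = list(NULL, .species))
  attr(states, "phases") <- phases
  states
}

#' Simulate a cohort of unsynchronized, non-interacting cells
#'
#' Each cell starts at a random phase of the no-treatment limit cycle
#' ([sampleInitialConditions()]) and is integrated independently under the
#' shared protocol. No cell-cell communication, division or death is
#' modelled; heterogeneity stems from initial phase only.
#'
#' @param params a [CircuitParams-class] object.
#' @param protocol a [Protocol-class] object.
#' @param nCells number of cells.
#' @param seed integer seed for the initial phases.
#' @param tSpan simulation span \code{c(t0, t1)} (h).
#' @param outputDt output step (h).
#' @return a [CohortResult-class] object.
#' @export
simulateCohort <- function(params, protocol = noTreatment(), nCells = 100L,
                           seed = 42L, tSpan = c(0, 336), outputDt = 0.5) {
  cycle <- limitCycle(params)
  init <- sampleInitialConditions(params, nCells, seed, cycle)
  times <- NULL
  states <- NULL
  for (i in seq_len(nCells)) {
    tr <- tryCatch(
      simulateCircuit(params, protocol, init[i, ], tSpan, outputDt),
      error = function(e)
        stop(sprintf("cell %d: %s", i, conditionMessage(e)), call. = FALSE))
    if (is.null(states)) {
      times <- tr@times
      states <- array(NA_real_, dim = c(nCells, length(times), 5L),
                      dimnames = list(NULL, NULL, .species))
    }
    states[i, , ] <- tr@states
  }
  new("CohortResult", nCells = as.integer(nCells), seed = as.integer(seed),
      times = times, states = states, protocolId = protocol@label,
      cycleCenter = cycle$center, cycleMid = cycle$mid)
}

.cohortTimeIndex <- function(cohort, t) {
  if (t < min(cohort@times) - 1e-9 || t > max(cohort@times) + 1e-9)
    stop("'t' outside the cohort time range")
  which.min(abs(cohort@times - t))
}

#' Population coefficient of variation
#'
#' Standard deviation over mean of one species across cells at time
#' \code{t}, using the population (divide-by-n) standard deviation.
#'
#' @param cohort a [CohortResult-class] object.
#' @param species species name, default \code{"K"} (CLK2).
#' @param t time (h) within the cohort's grid.
#' @return CV as a fraction.
#' @export
populationCV <- function(cohort, species = "K", t) {
  stopifnot(is(cohort, "CohortResult"))
  species <- match.arg(species, .species)
  x <- cohort@states[, .cohortTimeIndex(cohort, t), species]
  m <- mean(x)
  if (m == 0) stop("undefined CV: zero mean across cells")
  sqrt(mean((x - m)^2)) / m
}

#' Kuramoto-style synchronization order parameter
#'
#' Each cell's phase is the angle of its \code{(H - H_bar, C - C_bar)}
#' vector around the limit-cycle centroid \code{(H_bar, C_bar)}; the order
#' parameter is \code{R = |mean_i exp(i phi_i)|}: 1 for identical phases, 0
#' for phases spread uniformly around the cycle.
#'
#' @param cohort a [CohortResult-class] object with at least 2 cells.
#' @param t time (h) within the cohort's grid.
#' @return R in [0, 1].
#' @export
syncOrderParameter <- function(cohort, t) {
  stopifnot(is(cohort, "CohortResult"))
  if (cohort@nCells < 2L) stop("need at least 2 cells")
  i <- .cohortTimeIndex(cohort, t)
  dH <- cohort@states[, i, "H"] - cohort@cycleCenter[["H"]]
  dC <- cohort@states[, i, "C"] - cohort@cycleCenter[["C"]]
  if (all(sqrt(dH^2 + dC^2) < 1e-12))
    stop("undefined phase: all cells sit at the cycle centroid")
  phi <- atan2(dC, dH)
  Mod(mean(exp(1i * phi)))
}

#' Classify androgen-dependent vs androgen-independent phenotype
#'
#' AD (androgen-dependent): high HIPK1-PAGE4 and low CLK2-PAGE4
#' (\code{H > h_mid} and \code{C < c_mid}). AI (androgen-independent): low
#' HIPK1-PAGE4 and high CLK2-PAGE4 (\code{H < h_mid}, \code{C > c_mid}).
#' Anything else, boundaries included, is indeterminate. Default thresholds
#' are the limit-cycle midranges (see [limitCycle()]).
#'
#' @param state a named state vector, or a matrix with columns \code{H} and
#'   \code{C} (one row per cell).
#' @param h_mid,c_mid classification thresholds.
#' @return character vector of \code{"AD"}, \code{"AI"},
#'   \code{"indeterminate"}.
#' @export
classifyPhenotype <- function(state, h_mid, c_mid) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L,
                                           dimnames = list(NULL, names(state)))
  H <- state[, "H"]; C <- state[, "C"]
  out <- rep("indeterminate", length(H))
  out[H > h_mid & C < c_mid] <- "AD"
  out[H < h_mid & C > c_mid] <- "AI"
  out
}

#' Phenotype composition of a cohort at one time
#'
#' @param cohort a [CohortResult-class] object.
#' @param t time (h).
#' @return named fractions over \code{AD}, \code{AI},
#'   \code{indeterminate}.
#' @export
phenotypeFractions <- function(cohort, t) {
  i <- .cohortTimeIndex(cohort, t)
  lab <- classifyPhenotype(cohort@states[, i, ],
                           cohort@cycleMid[["h_mid"]],
                           cohort@cycleMid[["c_mid"]])
  tab <- table(factor(lab, levels = c("AD", "AI", "indeterminate")))
  fr <- as.vector(tab) / length(lab)
  names(fr) <- names(tab)
  fr
}
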