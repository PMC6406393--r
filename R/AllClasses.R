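#' Circuit parameter set for the PAGE4 phosphorylation circuit
#'
#' Holds rate constants and Hill parameters of the five-species circuit.
#' Concentrations are dimensionless, time is in hours. Species: W (WT-PAGE4),
#' H (HIPK1-PAGE4), C (CLK2-PAGE4), K (CLK2 kinase), A (AR activity).
#'
#' @slot g_W WT-PAGE4 production rate (conc/h).
#' @slot k_H HIPK1-catalysed conversion rate WT -> HIPK1 form (1/h).
#' @slot k_C CLK2-catalysed conversion rate constant HIPK1 -> CLK2 form
#'   (1/(conc*h)); multiplies the CLK2 kinase level.
#' @slot delta_W,delta_H,delta_C,delta_K,delta_A first-order degradation
#'   rates (1/h). The default set anchors \code{delta_W = log(2)/150}, the
#'   150-hour WT-PAGE4 half-life.
#' @slot g_A AR activity production scale (conc/h).
#' @slot g_K CLK2 production scale (conc/h).
#' @slot H0,n_H Hill threshold (conc) and coefficient for the inhibition of
#'   AR by HIPK1-PAGE4 (via c-Jun, lumped).
#' @slot A0,n_A Hill threshold and coefficient for the repression of CLK2
#'   by AR.
#' @slot beta_OE AR overexpression production boost (conc/h), active while a
#'   protocol's u_OE signal is on.
#'
#' @seealso [circuitParams()], [defaultCircuitParams()],
#'   [calibrateDefaultParams()]
#' @export
setClass("CircuitParams",
  representation(
    g_W = "numeric", k_H = "numeric", k_C = "numeric",
    delta_W = "numeric", delta_H = "numeric", delta_C = "numeric",
    delta_K = "numeric", delta_A = "numeric",
    g_A = "numeric", g_K = "numeric",
    H0 = "numeric", n_H = "numeric", A0 = "numeric", n_A = "numeric",
    beta_OE = "numeric"
  )
)

.circuitParamNames <- c(
  "g_W", "k_H", "k_C", "delta_W", "delta_H", "delta_C", "delta_K",
  "delta_A", "g_A", "g_K", "H0", "n_H", "A0", "n_A", "beta_OE"
)

setValidity("CircuitParams", function(object) {
  msgs <- character()
  for (nm in .circuitParamNames) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, sprintf("'%s' must be a single finite number", nm))
  }
  if (length(msgs)) return(msgs)
  # rates may be zero (ablation / decay-only studies) but never negative;
  # Hill thresholds must be strictly positive, coefficients at least 1
  rates <- c("g_W", "k_H", "k_C", "delta_W", "delta_H", "delta_C",
             "delta_K", "delta_A", "g_A", "g_K", "beta_OE")
  for (nm in rates)
    if (slot(object, nm) < 0)
      msgs <- c(msgs, sprintf("rate '%s' must be non-negative", nm))
  if (object@H0 <= 0) msgs <- c(msgs, "'H0' must be strictly positive")
  if (object@A0 <= 0) msgs <- c(msgs, "'A0' must be strictly positive")
  if (object@n_H < 1) msgs <- c(msgs, "'n_H' must be >= 1")
  if (object@n_A < 1) msgs <- c(msgs, "'n_A' must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Treatment protocol: piecewise-constant ADT / AR-overexpression signals
#'
#' A protocol is an ordered list of contiguous, non-overlapping half-open
#' segments \code{[t_start, t_end)} carrying the androgen-deprivation
#' efficacy \code{u_ADT} and the AR-overexpression drive \code{u_OE}, both
#' fractions in \code{[0, 1]}. The final segment may extend to \code{Inf} so
#' the protocol covers any simulation span.
#'
#' @slot segments data.frame with columns \code{t_start}, \code{t_end},
#'   \code{u_ADT}, \code{u_OE} (hours and fractions).
#' @slot label character protocol label.
#'
#' @seealso [constantADT()], [intermittentADT()], [batProtocol()],
#'   [protocolValue()]
#' @export
setClass("Protocol",
  representation(segments = "data.frame", label = "character")
)

setValidity("Protocol", function(object) {
  s <- object@segments
  need <- c("t_start", "t_end", "u_ADT", "u_OE")
  if (!all(need %in% names(s)))
    return(sprintf("segments must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(s) == 0L) return("protocol must contain at least one segment")
  if (any(s$t_end <= s$t_start)) return("segments must have t_end > t_start")
  if (nrow(s) > 1L &&
      any(abs(s$t_start[-1L] - s$t_end[-nrow(s)]) > 1e-9))
    return("segments must be contiguous and non-overlapping")
  u <- c(s$u_ADT, s$u_OE)
  if (any(u < 0 | u > 1)) return("u_ADT and u_OE must lie in [0, 1]")
  TRUE
})

#' Single-cell trajectory of the PAGE4 circuit
#'
#' @slot times strictly increasing output times (h).
#' @slot states numeric matrix, one row per time point, columns
#'   \code{W, H, C, K, A}.
#' @slot paramsId,protocolId provenance tags.
#'
#' @seealso [simulateCircuit()], [speciesSeries()], [detectPeriod()]
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix",
                 paramsId = "character", protocolId = "character")
)

setValidity("Trajectory", function(object) {
  if (length(object@times) != nrow(object@states))
    return("length(times) must equal nrow(states)")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!identical(colnames(object@states), .species))
    return("states columns must be W, H, C, K, A")
  if (any(!is.finite(object@states)))
    return("states must be finite")
  if (any(object@states < -1e-9))
    return("states must be non-negative (floor -1e-9)")
  TRUE
})

#' Cohort simulation result
#'
#' Per-cell trajectories of a population of non-interacting cells sharing
#' one parameter set and protocol but starting at randomized phases of the
#' no-treatment limit cycle.
#'
#' @slot nCells number of cells.
#' @slot seed integer seed that generated the initial conditions.
#' @slot times shared output times (h).
#' @slot states numeric array \code{[cell, time, species]}.
#' @slot protocolId protocol label.
#' @slot cycleCenter named numeric \code{(H, C)}: centroid of the
#'   no-treatment limit cycle in the (H, C) plane, the reference point for
#'   phase angles.
#' @slot cycleMid named numeric \code{(h_mid, c_mid)}: limit-cycle midrange
#'   thresholds used by [classifyPhenotype()].
#'
#' @seealso [simulateCohort()], [populationCV()], [syncOrderParameter()]
#' @export
setClass("CohortResult",
  representation(nCells = "integer", seed = "integer", times = "numeric",
                 states = "array", protocolId = "character",
                 cycleCenter = "numeric", cycleMid = "numeric")
)

setValidity("CohortResult", function(object) {
  d <- dim(object@states)
  if (length(d) != 3L) return("states must be a 3-d array")
  if (d[1L] != object@nCells) return("dim 1 of states must equal nCells")
  if (d[2L] != length(object@times)) return("dim 2 must match times")
  if (d[3L] != 5L) return("dim 3 must hold the five species")
  if (object@nCells < 1L) return("nCells must be >= 1")
  TRUE
})

#' Oscillation summary
#'
#' @slot period mean successive peak spacing (h); \code{NA} when not
#'   oscillating.
#' @slot amplitude peak-to-peak range after burn-in (conc).
#' @slot peakTimes strictly increasing peak times (h).
#' @slot isOscillating logical flag (at least 3 peaks and amplitude at least
#'   1 percent of the mean).
#'
#' @seealso [detectPeriod()]
#' @export
setClass("OscillationSummary",
  representation(period = "numeric", amplitude = "numeric",
                 peakTimes = "numeric", isOscillating = "logical")
)

setValidity("OscillationSummary", function(object) {
  if (object@isOscillating && !(is.finite(object@period) && object@period > 0))
    return("period must be positive when oscillating")
  if (length(object@peakTimes) > 1L && any(diff(object@peakTimes) <= 0))
    return("peakTimes must be strictly increasing")
  TRUE
})

#' C-alpha conformational ensemble
#'
#' @slot coords numeric array \code{[conformer, residue, 3]} in Angstrom,
#'   1-based residue numbering.
#' @slot labels optional residue names (character(0) when absent).
#'
#' @seealso [generateEnsemble()], [readEnsembleXYZ()], [contactMap()]
#' @export
setClass("Ensemble",
  representation(coords = "array", labels = "character")
)

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3L] != 3L)
    return("coords must be a [conformer, residue, 3] array")
  if (any(!is.finite(object@coords))) return("coords must contain no NaN")
  if (length(object@labels) && length(object@labels) != d[2L])
    return("labels length must match the number of residues")
  TRUE
})

#' Ensemble-averaged contact probability map
#'
#' @slot map symmetric L x L matrix of contact probabilities in [0, 1];
#'   the diagonal band \code{|i - j| < minSeqSep} is zero.
#' @slot cutoff contact distance cutoff (Angstrom).
#' @slot minSeqSep minimum sequence separation.
#'
#' @seealso [contactMap()]
#' @export
setClass("ContactMap",
  representation(map = "matrix", cutoff = "numeric", minSeqSep = "numeric")
)

setValidity("ContactMap", function(object) {
  m <- object@map
  if (nrow(m) != ncol(m)) return("map must be square")
  if (max(abs(m - t(m))) > 1e-12) return("map must be symmetric")
  if (any(m < 0 | m > 1)) return("entries must lie in [0, 1]")
  TRUE
})

#' Contact-based PCA result
#'
#' Principal modes of the covariance of per-conformer binary contact vectors
#' over retained residue pairs.
#'
#' @slot modes p x k matrix of orthonormal mode coefficients (one column per
#'   mode); each mode's largest-magnitude coefficient is positive.
#' @slot eigenvalues non-negative variances, sorted descending.
#' @slot pairIndex data.frame with columns \code{i}, \code{j} mapping rows of
#'   \code{modes} to residue pairs.
#'
#' @seealso [contactPCA()]
#' @export
setClass("ContactPCA",
  representation(modes = "matrix", eigenvalues = "numeric",
                 pairIndex = "data.frame")
)

setValidity("ContactPCA", function(object) {
  if (nrow(object@pairIndex) != nrow(object@modes))
    return("pairIndex must have one row per mode coefficient")
  ev <- object@eigenvalues
  if (any(ev < -1e-12)) return("eigenvalues must be non-negative")
  if (length(ev) > 1L && any(diff(ev) > 1e-12))
    return("eigenvalues must be sorted descending")
  g <- crossprod(object@modes)
  if (max(abs(g - diag(ncol(object@modes)))) > 1e-8)
    return("modes must be orthonormal")
  TRUE
})

#' Synthetic-ensemble preset
#'
#' Emulation parameters of a phospho-form: loop occupancies, mutual
#' exclusivity, and a solvent-quality expansion factor driving the
#' persistence of the self-avoiding walk.
#'
#' @slot name preset name ("WT", "HIPK1", "CLK2" or custom).
#' @slot pNLoop probability that a conformer carries the N-loop restraint
#'   (N-motif 4-12 near the central acidic region 43-62).
#' @slot pCLoop probability of the C-loop restraint (C-motif 82-95 near the
#'   central acidic region).
#' @slot exclusivity logical; when TRUE at most one restraint per conformer
#'   (requires \code{pNLoop + pCLoop <= 1}).
#' @slot expansion dimensionless solvent-quality factor >= 1; larger values
#'   stiffen the walk and expand the chain.
#'
#' @seealso [ensemblePreset()], [defaultPresets()], [generateEnsemble()]
#' @export
setClass("EnsemblePreset",
  representation(name = "character", pNLoop = "numeric", pCLoop = "numeric",
                 exclusivity = "logical", expansion = "numeric")
)

setValidity("EnsemblePreset", function(object) {
  p <- c(object@pNLoop, object@pCLoop)
  if (any(p < 0 | p > 1)) return("loop probabilities must lie in [0, 1]")
  if (object@exclusivity && sum(p) > 1 + 1e-12)
    return("pNLoop + pCLoop must be <= 1 under exclusivity")
  if (object@expansion < 1) return("expansion must be >= 1")
  TRUE
})
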