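#' Construct a synthetic-ensemble preset
#'
#' @param name preset name.
#' @param pNLoop,pCLoop per-conformer probabilities of the N-loop
#'   (N-motif 4-12 near the central acidic region 43-62) and C-loop
#'   (C-motif 82-95 near the central acidic region) restraints.
#' @param exclusivity when TRUE at most one restraint applies per conformer.
#' @param expansion solvent-quality factor >= 1 (persistence of the walk).
#' @return an [EnsemblePreset-class] object.
#' @export
ensemblePreset <- function(name, pNLoop = 0, pCLoop = 0,
                           exclusivity = FALSE, expansion = 1) {
  new("EnsemblePreset", name = name, pNLoop = pNLoop, pCLoop = pCLoop,
      exclusivity = exclusivity, expansion = expansion)
}

#' Default presets for the three PAGE4 phospho-forms
#'
#' Emulation parameters (calibration knobs of the generator, not measured
#' quantities) chosen to reproduce the qualitative ensemble signatures of
#' the three phospho-forms:
#' \describe{
#'   \item{WT}{frequent N-loop (\code{pNLoop = 0.6}), no C-loop, compact.}
#'   \item{HIPK1}{N- and C-loops at 0.45 each, mutually exclusive -- the two
#'     termini take turns contacting the central acidic region, yielding
#'     anti-correlated loop modes.}
#'   \item{CLK2}{no loops and \code{expansion = 1.8}: hyper-phosphorylation
#'     eradicates loop formation and expands the chain, most prominently in
#'     the N-terminal half.}
#' }
#'
#' @return named list of [EnsemblePreset-class] objects (WT, HIPK1, CLK2).
#' @export
defaultPresets <- function() {
  list(WT = ensemblePreset("WT", pNLoop = 0.6),
       HIPK1 = ensemblePreset("HIPK1", pNLoop = 0.45, pCLoop = 0.45,
                              exclusivity = TRUE),
       CLK2 = ensemblePreset("CLK2", expansion = 1.8))
}

.bondLength <- 3.8    # virtual C-alpha bond (Angstrom)
.hardSphereR <- 2.0   # residue hard-sphere radius; non-bonded pairs >= 4.0 A
.loopCutoff <- 9.0    # centroid-centroid restraint distance (Angstrom)

.regionCentroidDistance <- function(xyz, a, b) {
  ca <- colMeans(xyz[a, , drop = FALSE])
  cb <- colMeans(xyz[b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Generate one conformer from a preset
#'
#' Builds a self-avoiding random walk with fixed 3.8 Angstrom virtual bonds
#' and hard-sphere radius 2.0 Angstrom; the persistence bias grows with the
#' preset's \code{expansion} factor (direction =
#' normalize((expansion - 1) * previous + random unit vector)). Loop
#' restraints (region-centroid distance <= 9 Angstrom) are enforced by
#' rejection sampling: whole chains are redrawn until the restraint holds.
#' Uses the current RNG state; see [generateEnsemble()] for seeded,
#' reproducible ensembles.
#'
#' @param preset an [EnsemblePreset-class] object.
#' @param chainLength number of residues, default 102.
#' @param maxAttempts rejection-sampling budget per conformer.
#' @return L x 3 coordinate matrix (Angstrom).
#' @export
generateConformer <- function(preset, chainLength = 102L,
                              maxAttempts = 10000L) {
  stopifnot(is(preset, "EnsemblePreset"))
  reg <- pageRegions()
  needN <- FALSE; needC <- FALSE
  if (preset@exclusivity) {
    u <- stats::runif(1)
    if (u < preset@pNLoop) needN <- TRUE
    else if (u < preset@pNLoop + preset@pCLoop) needC <- TRUE
  } else {
    needN <- stats::runif(1) < preset@pNLoop
    needC <- stats::runif(1) < preset@pCLoop
  }
  kappa <- preset@expansion - 1
  for (att in seq_len(maxAttempts)) {
    xyz <- .sawChain(as.integer(chainLength), .bondLength, 2 * .hardSphereR,
                     kappa)
    okN <- !needN || .regionCentroidDistance(xyz, reg$n_motif,
                                             reg$central_acidic) <= .loopCutoff
    okC <- !needC || .regionCentroidDistance(xyz, reg$c_motif,
                                             reg$central_acidic) <= .loopCutoff
    if (okN && okC) {
      attr(xyz, "loop") <- if (needN) "N" else if (needC) "C" else "none"
      return(xyz)
    }
  }
  stop(sprintf("loop restraint unsatisfiable after %d attempts", maxAttempts))
}

#' Generate a synthetic conformational ensemble
#'
#' Draws \code{n} independent conformers from a preset (see
#' [generateConformer()]). Deterministic given \code{seed}: the same seed
#' yields a byte-identical ensemble.
#'
#' @param preset an [EnsemblePreset-class] object.
#' @param n number of conformers.
#' @param seed integer RNG seed (default 42).
#' @param chainLength number of residues, default 102.
#' @return an [Ensemble-class] object; the restraint drawn for each
#'   conformer ("N", "C" or "none") is recorded in
#'   \code{attr(coords, "loops")} retrievable via [ensembleLoops()].
#' @export
generateEnsemble <- function(preset, n, seed = 42L, chainLength = 102L) {
  stopifnot(n >= 1L)
  loops <- character(n)
  coords <- array(NA_real_, dim = c(n, chainLength, 3L))
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n)) {
      xyz <- generateConformer(preset, chainLength)
      loops[k] <- attr(xyz, "loop")
      coords[k, , ] <- xyz
    }
  })
  ens <- new("Ensemble", coords = coords, labels = character(0))
  attr(ens@coords, "loops") <- loops
  ens
}

#' @rdname generateEnsemble
#' @param ensemble an [Ensemble-class] produced by [generateEnsemble()].
#' @return \code{ensembleLoops}: character vector of per-conformer restraint
#'   bookkeeping ("N", "C", "none"), or NULL for ensembles from other
#'   sources.
#' @export
ensembleLoops <- function(ensemble) {
  attr(ensemble@coords, "loops")
}
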