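#' @name page4dyn-accessors
#' @title Accessors for page4dyn classes
#'
#' @description Accessor generics: \code{timePoints} and \code{speciesMatrix}
#' expose a trajectory's grid and state matrix; \code{speciesSeries} extracts
#' one species; \code{nConformers}, \code{chainLength} and \code{conformer}
#' expose ensemble dimensions and single conformers; \code{contactMatrix}
#' returns the probability matrix of a contact map.
#'
#' @param x a page4dyn object.
#' @param species one of \code{"W"}, \code{"H"}, \code{"C"}, \code{"K"},
#'   \code{"A"}.
#' @param i conformer index.
NULL

#' @rdname page4dyn-accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname page4dyn-accessors
#' @export
setGeneric("speciesMatrix", function(x) standardGeneric("speciesMatrix"))

#' @rdname page4dyn-accessors
#' @export
setGeneric("speciesSeries", function(x, species)
  standardGeneric("speciesSeries"))

#' @rdname page4dyn-accessors
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' @rdname page4dyn-accessors
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))

#' @rdname page4dyn-accessors
#' @export
setGeneric("conformer", function(x, i) standardGeneric("conformer"))

#' @rdname page4dyn-accessors
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' Radius of gyration
#'
#' Root-mean-square distance of residues to their centroid, unweighted:
#' \code{sqrt(mean(|r_i - r_centroid|^2))}. For an [Ensemble] the value is
#' computed per conformer.
#'
#' @param x an L x 3 coordinate matrix (Angstrom) or an [Ensemble].
#' @return numeric: a scalar for a matrix, a vector over conformers for an
#'   ensemble.
#'
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(10, 0, 0)))  # 5
#' @export
setGeneric("radiusOfGyration", function(x) standardGeneric("radiusOfGyration"))

#' @rdname Trajectory-class
setMethod("timePoints", "Trajectory", function(x) x@times)

#' @rdname Trajectory-class
setMethod("speciesMatrix", "Trajectory", function(x) x@states)

#' @rdname Trajectory-class
setMethod("speciesSeries", "Trajectory", function(x, species) {
  species <- match.arg(species, .species)
  x@states[, species]
})

#' @rdname CohortResult-class
setMethod("timePoints", "CohortResult", function(x) x@times)

#' @rdname Ensemble-class
setMethod("nConformers", "Ensemble", function(x) dim(x@coords)[1L])

#' @rdname Ensemble-class
setMethod("chainLength", "Ensemble", function(x) dim(x@coords)[2L])

#' @rdname Ensemble-class
setMethod("conformer", "Ensemble", function(x, i) {
  m <- x@coords[i, , , drop = TRUE]
  dim(m) <- c(dim(x@coords)[2L], 3L)
  m
})

#' @rdname ContactMap-class
setMethod("contactMatrix", "ContactMap", function(x) x@map)

setMethod("show", "CircuitParams", function(object) {
  cat("CircuitParams (dimensionless conc, time in h)\n")
  v <- vapply(.circuitParamNames, function(nm) slot(object, nm), numeric(1))
  print(signif(v, 5))
  cat(sprintf("  WT-PAGE4 half-life: %.1f h\n", log(2) / object@delta_W))
})

setMethod("show", "Protocol", function(object) {
  cat(sprintf("Protocol '%s': %d segment(s)\n", object@label,
              nrow(object@segments)))
  print(utils::head(object@segments, 8))
  if (nrow(object@segments) > 8) cat("  ...\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%.1f, %.1f] h (params %s, protocol %s)\n",
              length(object@times), min(object@times), max(object@times),
              object@paramsId, object@protocolId))
})

setMethod("show", "CohortResult", function(object) {
  cat(sprintf("CohortResult: %d cells x %d time points (protocol %s, seed %d)\n",
              object@nCells, length(object@times), object@protocolId,
              object@seed))
})

setMethod("show", "OscillationSummary", function(object) {
  if (object@isOscillating)
    cat(sprintf("Oscillating: period %.2f h, peak-to-peak amplitude %.4g (%d peaks)\n",
                object@period, object@amplitude, length(object@peakTimes)))
  else
    cat("Not oscillating (fewer than 3 peaks or amplitude < 1% of mean)\n")
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d conformers x %d residues (C-alpha, Angstrom)\n",
              nConformers(object), chainLength(object)))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d x %d, cutoff %.2f A, |i-j| >= %d\n",
              nrow(object@map), ncol(object@map), object@cutoff,
              as.integer(object@minSeqSep)))
})

setMethod("show", "ContactPCA", function(object) {
  cat(sprintf("ContactPCA: %d modes over %d contact pairs\n",
              ncol(object@modes), nrow(object@modes)))
  cat("  eigenvalues:", signif(utils::head(object@eigenvalues, 5), 4), "\n")
})

setMethod("show", "EnsemblePreset", function(object) {
  cat(sprintf("EnsemblePreset '%s': pNLoop=%.2f pCLoop=%.2f exclusive=%s expansion=%.2f\n",
              object@name, object@pNLoop, object@pCLoop,
              object@exclusivity, object@expansion))
})
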