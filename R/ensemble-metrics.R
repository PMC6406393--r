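#' PAGE4 sequence regions
#'
#' The canonical segments of the 102-residue PAGE4 chain (1-based,
#' inclusive): N-motif 4-12, central acidic region 43-62, transiently
#' helical region 65-73, C-motif 82-95.
#'
#' @return named list of integer residue vectors.
#' @export
pageRegions <- function() {
  list(n_motif = 4:12, central_acidic = 43:62, transient_helix = 65:73,
       c_motif = 82:95)
}

#' Construct an ensemble from a coordinate array
#'
#' @param coords numeric array \code{[conformer, residue, 3]} (Angstrom),
#'   or a single L x 3 matrix for a one-conformer ensemble.
#' @param labels optional residue names.
#' @return an [Ensemble-class] object.
#' @export
ensembleFromArray <- function(coords, labels = character(0)) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  new("Ensemble", coords = coords, labels = labels)
}

setMethod("radiusOfGyration", "matrix", function(x) {
  if (nrow(x) < 2L) stop("radius of gyration needs at least 2 residues")
  ctr <- colMeans(x)
  sqrt(mean((x[, 1L] - ctr[1L])^2 + (x[, 2L] - ctr[2L])^2 +
              (x[, 3L] - ctr[3L])^2))
})

setMethod("radiusOfGyration", "Ensemble", function(x) {
  if (chainLength(x) < 2L) stop("radius of gyration needs at least 2 residues")
  vapply(seq_len(nConformers(x)),
         function(i) radiusOfGyration(conformer(x, i)), numeric(1))
})

#' Free-energy profile of a scalar observable
#'
#' Histograms the samples into \code{nBins} equal-width bins, converts
#' counts to probabilities P and returns \code{F = -kT * log(P)}, shifted so
#' the minimum is 0. Empty bins are masked as \code{NA} (never +/-Inf).
#'
#' @param samples numeric observable samples (>= 100 unless
#'   \code{allowSmall}).
#' @param nBins number of bins (>= 5).
#' @param kT thermal energy scale; default 1 (dimensionless units).
#' @param allowSmall skip the minimum-sample check (for toy cases).
#' @return data.frame with columns \code{center} (bin centers) and \code{F}.
#' @examples
#' prof <- freeEnergyProfile(rnorm(1e4), nBins = 40)
#' @export
freeEnergyProfile <- function(samples, nBins = 50, kT = 1,
                              allowSmall = FALSE) {
  if (!allowSmall && length(samples) < 100L)
    stop("need at least 100 samples for a free-energy profile")
  if (nBins < 5L) stop("'nBins' must be >= 5")
  rng <- range(samples)
  if (diff(rng) == 0) {
    warning("all samples identical: degenerate single-bin profile")
    return(data.frame(center = rng[1L], F = 0))
  }
  h <- graphics::hist(samples, breaks = seq(rng[1L], rng[2L],
                                            length.out = nBins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  F <- ifelse(p > 0, -kT * log(p), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  data.frame(center = h$mids, F = F)
}

#' Distances and distance distribution for one residue pair
#'
#' \code{pairDistances} returns the per-conformer distance between residues
#' \code{i} and \code{j}; \code{pairwiseDistanceDistribution} bins them into
#' a normalized histogram (probabilities summing to 1). The pairs measured
#' in the smFRET experiments, (18, 63) and (63, 102), are the conventional
#' choices for the N- and C-terminal halves.
#'
#' @param ensemble an [Ensemble-class] object.
#' @param i,j 1-based residue indices with \code{i < j}.
#' @param nBins number of histogram bins.
#' @return \code{pairDistances}: numeric vector (Angstrom);
#'   \code{pairwiseDistanceDistribution}: data.frame with columns
#'   \code{center}, \code{p}.
#' @export
pairDistances <- function(ensemble, i, j) {
  stopifnot(is(ensemble, "Ensemble"))
  L <- chainLength(ensemble)
  if (i == j) stop("'i' and 'j' must differ")
  if (i < 1L || j > L || i > j) stop("need 1 <= i < j <= chain length")
  d <- ensemble@coords[, i, , drop = FALSE] -
    ensemble@coords[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, ncol = 3L)^2))
}

#' @rdname pairDistances
#' @export
pairwiseDistanceDistribution <- function(ensemble, i, j, nBins = 50) {
  d <- pairDistances(ensemble, i, j)
  rng <- range(d)
  if (diff(rng) == 0) {
    # point mass: all conformers identical for this pair
    return(data.frame(center = rng[1L], p = 1))
  }
  h <- graphics::hist(d, breaks = seq(rng[1L], rng[2L],
                                      length.out = nBins + 1L), plot = FALSE)
  data.frame(center = h$mids, p = h$counts / sum(h$counts))
}

# per-conformer binary contact matrix over all residue pairs
.contactIndicator <- function(xyz, cutoff, minSeqSep) {
  dm <- as.matrix(stats::dist(xyz))
  ind <- dm <= cutoff
  L <- nrow(xyz)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  ind[sep < minSeqSep] <- FALSE
  ind
}

#' Ensemble-averaged contact map
#'
#' Entry (i, j) is the fraction of conformers in which residues i and j lie
#' within \code{cutoff} Angstrom (C-alpha to C-alpha); pairs closer than
#' \code{minSeqSep} in sequence are masked to zero.
#'
#' @param ensemble an [Ensemble-class] object.
#' @param cutoff contact cutoff (Angstrom), default 9.5.
#' @param minSeqSep minimum sequence separation, default 3.
#' @return a [ContactMap-class] object.
#' @export
contactMap <- function(ensemble, cutoff = 9.5, minSeqSep = 3) {
  stopifnot(is(ensemble, "Ensemble"))
  n <- nConformers(ensemble)
  L <- chainLength(ensemble)
  acc <- matrix(0, L, L)
  for (k in seq_len(n))
    acc <- acc + .contactIndicator(conformer(ensemble, k), cutoff, minSeqSep)
  new("ContactMap", map = acc / n, cutoff = cutoff, minSeqSep = minSeqSep)
}

#' Mean contact probability over a region block
#'
#' Convenience summary of a contact map: the mean probability over the
#' rectangular block \code{regionA} x \code{regionB}.
#'
#' @param cm a [ContactMap-class] object.
#' @param regionA,regionB integer residue vectors.
#' @return mean contact probability.
#' @export
blockContactProbability <- function(cm, regionA, regionB) {
  stopifnot(is(cm, "ContactMap"))
  mean(cm@map[regionA, regionB])
}

# retained upper-triangle pairs at a sequence separation
.contactPairs <- function(L, minSeqSep) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= minSeqSep, , drop = FALSE]
  data.frame(i = idx[, 1L], j = idx[, 2L])
}

#' Contact-based principal component analysis
#'
#' Each conformer is encoded as a binary contact vector over the retained
#' residue pairs; the principal modes are the eigenvectors of the pair-space
#' covariance matrix across conformers (divide-by-(n-1) convention),
#' computed via singular value decomposition of the centered contact
#' matrix. Anti-correlated loadings on two sets of pairs indicate mutually
#' exclusive contact formation (e.g. the two looping motions of
#' HIPK1-PAGE4). Sign convention: each mode's largest-magnitude coefficient
#' is positive.
#'
#' @param ensemble an [Ensemble-class] object with at least
#'   \code{nModes + 1} conformers.
#' @param cutoff,minSeqSep contact definition (see [contactMap()]).
#' @param nModes number of modes to return, default 2.
#' @return a [ContactPCA-class] object.
#' @export
contactPCA <- function(ensemble, cutoff = 9.5, minSeqSep = 3, nModes = 2) {
  stopifnot(is(ensemble, "Ensemble"))
  n <- nConformers(ensemble)
  if (n < nModes + 1L) stop("need at least nModes + 1 conformers")
  L <- chainLength(ensemble)
  pairs <- .contactPairs(L, minSeqSep)
  X <- matrix(0, n, nrow(pairs))
  for (k in seq_len(n)) {
    ind <- .contactIndicator(conformer(ensemble, k), cutoff, minSeqSep)
    X[k, ] <- ind[cbind(pairs$i, pairs$j)]
  }
  Xc <- sweep(X, 2L, colMeans(X))
  if (all(abs(Xc) < 1e-12))
    stop("degenerate covariance: the contact set has zero variance")
  sv <- svd(Xc, nu = 0, nv = nModes)
  ev <- sv$d^2 / (n - 1)
  modes <- sv$v
  # fix signs so the largest-magnitude coefficient of each mode is positive
  for (m in seq_len(ncol(modes))) {
    top <- which.max(abs(modes[, m]))
    if (modes[top, m] < 0) modes[, m] <- -modes[, m]
  }
  new("ContactPCA", modes = modes,
      eigenvalues = ev[seq_len(min(length(ev), nModes))], pairIndex = pairs)
}

#' Geometric turn propensity
#'
#' A residue i is flagged turn-like in a conformer when the C-alpha pair
#' (i, i+3) lies within 7 Angstrom and the four residues i..i+3 are not
#' collinear (both internal virtual-bond angles below 150 degrees). The
#' propensity is the fraction of conformers flagged. This geometric
#' criterion stands in for secondary-structure assignment on C-alpha-only
#' ensembles; residues 1-3 and the last three are reported as \code{NA}.
#'
#' @param ensemble an [Ensemble-class] object with at least 4 residues.
#' @param dCut distance cutoff (Angstrom), default 7.
#' @param angleCut collinearity cutoff (degrees), default 150.
#' @return numeric vector of per-residue propensities (with \code{NA} at
#'   the chain ends).
#' @export
turnPropensity <- function(ensemble, dCut = 7.0, angleCut = 150) {
  stopifnot(is(ensemble, "Ensemble"))
  L <- chainLength(ensemble)
  if (L < 4L) stop("turn propensity needs a chain of at least 4 residues")
  n <- nConformers(ensemble)
  counts <- numeric(L)
  idx <- 4:(L - 3L)
  for (k in seq_len(n)) {
    xyz <- conformer(ensemble, k)
    b <- diff(xyz)                       # virtual bond vectors
    bn <- sqrt(rowSums(b^2))
    # angle at residue m+1 between bonds m and m+1 (180 deg = straight)
    cosang <- rowSums(b[-nrow(b), , drop = FALSE] *
                        b[-1L, , drop = FALSE]) /
      (bn[-length(bn)] * bn[-1L])
    ang <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    for (i in idx) {
      d <- sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2))
      if (d < dCut && max(ang[i], ang[i + 1L]) < angleCut)
        counts[i] <- counts[i] + 1
    }
  }
  prop <- counts / n
  prop[-idx] <- NA_real_
  prop
}
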