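# strict local maxima with topographic prominence
.findPeaks <- function(x, minProminence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]; h <- x[p]
    # walk outwards to the nearest higher ground on each side; the key saddle
    # is the higher of the two intervening minima
    lmin <- h; i <- p - 1L
    while (i >= 1L && x[i] <= h) { if (x[i] < lmin) lmin <- x[i]; i <- i - 1L }
    if (i < 1L) lmin <- min(x[1:p])
    rmin <- h; i <- p + 1L
    while (i <= n && x[i] <= h) { if (x[i] < rmin) rmin <- x[i]; i <- i + 1L }
    if (i > n) rmin <- min(x[p:n])
    keep[k] <- (h - max(lmin, rmin)) >= minProminence
  }
  cand[keep]
}

.sliceTrajectory <- function(traj, t0, t1) {
  sel <- traj@times >= t0 & traj@times <= t1
  new("Trajectory", times = traj@times[sel],
      states = traj@states[sel, , drop = FALSE],
      paramsId = traj@paramsId, protocolId = traj@protocolId)
}

#' Detect oscillation period and amplitude
#'
#' Peaks are local maxima of the chosen species after \code{burnIn} whose
#' topographic prominence is at least 5 percent of the post-burn-in range.
#' The period is the mean successive peak spacing; the trajectory is flagged
#' oscillating when at least 3 peaks are found and the peak-to-peak
#' amplitude is at least 1 percent of the mean level. With fewer than 3
#' peaks the summary carries \code{isOscillating = FALSE} and an undefined
#' period (no error is raised).
#'
#' @param traj a [Trajectory-class] object.
#' @param species species name, default \code{"H"} (HIPK1-PAGE4).
#' @param burnIn transient to discard (h).
#' @param prominenceFrac prominence threshold as a fraction of the range.
#' @return an [OscillationSummary-class] object.
#' @export
detectPeriod <- function(traj, species = "H", burnIn = 0,
                         prominenceFrac = 0.05) {
  stopifnot(is(traj, "Trajectory"))
  sel <- traj@times >= burnIn
  if (sum(sel) < 3L) stop("trajectory too short after burn-in")
  tt <- traj@times[sel]
  x <- traj@states[sel, match.arg(species, .species)]
  rng <- diff(range(x))
  amp <- rng
  pk <- if (rng > 0) .findPeaks(x, prominenceFrac * rng) else integer(0)
  m <- mean(x)
  oscillating <- length(pk) >= 3L && amp >= 0.01 * abs(m)
  new("OscillationSummary",
      period = if (length(pk) >= 2L) mean(diff(tt[pk])) else NA_real_,
      amplitude = amp,
      peakTimes = tt[pk],
      isOscillating = oscillating)
}

#' Time for a treatment to quench oscillations
#'
#' The pre-treatment oscillation (over \code{[burnIn, tOn)}) defines a
#' reference period and peak-to-peak amplitude. The quench time is the first
#' \code{t >= tOn} at which the peak-to-peak range of the species inside the
#' sliding window \code{[t, t + period]} falls below \code{frac} times the
#' pre-treatment amplitude; \code{Inf} is returned when the amplitude never
#' falls that far within the trajectory.
#'
#' @param traj a [Trajectory-class] object extending beyond \code{tOn}.
#' @param species species name, default \code{"H"}.
#' @param tOn treatment onset (h); the trajectory must oscillate before it.
#' @param frac amplitude fraction defining "quenched" (default 0.05).
#' @param burnIn pre-treatment transient to discard (h).
#' @return quench time (h, absolute), or \code{Inf}.
#' @export
quenchTime <- function(traj, species = "H", tOn, frac = 0.05, burnIn = 0) {
  stopifnot(is(traj, "Trajectory"))
  if (tOn <= burnIn) stop("'tOn' must exceed 'burnIn'")
  pre <- detectPeriod(.sliceTrajectory(traj, burnIn, tOn), species)
  if (!pre@isOscillating)
    stop("no established pre-treatment oscillation before tOn")
  period <- pre@period
  ampPre <- pre@amplitude
  species <- match.arg(species, .species)
  tt <- traj@times
  x <- traj@states[, species]
  lastStart <- max(tt) - period
  starts <- which(tt >= tOn & tt <= lastStart)
  for (i in starts) {
    w <- x[tt >= tt[i] & tt <= tt[i] + period]
    if (diff(range(w)) < frac * ampPre) return(tt[i])
  }
  Inf
}
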