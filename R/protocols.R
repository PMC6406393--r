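.protocol <- function(segments, label) {
  rownames(segments) <- NULL
  new("Protocol", segments = segments, label = label)
}

#' Treatment protocols
#'
#' Constructors for the piecewise-constant treatment signals consumed by
#' [simulateCircuit()]. Segments are half-open intervals
#' \code{[t_start, t_end)} in hours (left-closed, right-open), and every
#' protocol covers \code{[0, Inf)}.
#'
#' \describe{
#'   \item{\code{noTreatment()}}{u_ADT = u_OE = 0 throughout.}
#'   \item{\code{constantADT(tOn, u)}}{androgen-deprivation therapy at
#'     efficacy \code{u} from \code{tOn} onward.}
#'   \item{\code{intermittentADT(onDuration, offDuration, tStart, nCycles)}}{
#'     \code{nCycles} alternating blocks of full ADT and drug holiday,
#'     starting at \code{tStart}; untreated afterwards.}
#'   \item{\code{batProtocol(block, tStart, nCycles)}}{bipolar androgen
#'     treatment: alternating AR-overexpression and full-ADT blocks of
#'     length \code{block} (default 336 h, i.e. two weeks each).}
#' }
#'
#' @param tOn,tStart treatment onset (h, >= 0).
#' @param u ADT efficacy in [0, 1].
#' @param onDuration,offDuration,block block durations (h, > 0).
#' @param nCycles number of cycles (>= 1).
#' @return a [Protocol-class] object.
#' @examples
#' protocolValue(constantADT(500, 1), c(499, 501))
#' intermittentADT(168, 168, 0, 2)
#' @name protocols
NULL

#' @rdname protocols
#' @export
noTreatment <- function() {
  .protocol(data.frame(t_start = 0, t_end = Inf, u_ADT = 0, u_OE = 0),
            "none")
}

#' @rdname protocols
#' @export
constantADT <- function(tOn = 0, u = 1) {
  if (tOn < 0) stop("'tOn' must be >= 0")
  if (u < 0 || u > 1) stop("'u' must lie in [0, 1]")
  seg <- if (tOn > 0)
    data.frame(t_start = c(0, tOn), t_end = c(tOn, Inf),
               u_ADT = c(0, u), u_OE = 0)
  else
    data.frame(t_start = 0, t_end = Inf, u_ADT = u, u_OE = 0)
  .protocol(seg, sprintf("adt:t_on=%g,u=%g", tOn, u))
}

#' @rdname protocols
#' @export
intermittentADT <- function(onDuration = 168, offDuration = 168,
                            tStart = 0, nCycles = 5L) {
  if (onDuration <= 0 || offDuration <= 0)
    stop("durations must be positive")
  if (nCycles < 1L) stop("intermittent ADT needs at least one cycle")
  if (tStart < 0) stop("'tStart' must be >= 0")
  starts <- tStart + (seq_len(nCycles) - 1L) * (onDuration + offDuration)
  seg <- data.frame(
    t_start = as.vector(rbind(starts, starts + onDuration)),
    t_end = as.vector(rbind(starts + onDuration,
                            starts + onDuration + offDuration)),
    u_ADT = rep(c(1, 0), nCycles), u_OE = 0)
  if (tStart > 0)
    seg <- rbind(data.frame(t_start = 0, t_end = tStart, u_ADT = 0,
                            u_OE = 0), seg)
  seg$t_end[nrow(seg)] <- Inf  # final holiday extends indefinitely
  .protocol(seg, sprintf("iadt:on=%g,off=%g,t0=%g,n=%d", onDuration,
                         offDuration, tStart, nCycles))
}

#' @rdname protocols
#' @export
batProtocol <- function(block = 336, tStart = 0, nCycles = 3L) {
  if (block <= 0) stop("'block' must be positive")
  if (nCycles < 1L) stop("BAT needs at least one cycle")
  if (tStart < 0) stop("'tStart' must be >= 0")
  starts <- tStart + (seq_len(nCycles) - 1L) * 2 * block
  seg <- data.frame(
    t_start = as.vector(rbind(starts, starts + block)),
    t_end = as.vector(rbind(starts + block, starts + 2 * block)),
    u_ADT = rep(c(0, 1), nCycles),
    u_OE = rep(c(1, 0), nCycles))
  if (tStart > 0)
    seg <- rbind(data.frame(t_start = 0, t_end = tStart, u_ADT = 0,
                            u_OE = 0), seg)
  tail_seg <- data.frame(t_start = seg$t_end[nrow(seg)], t_end = Inf,
                         u_ADT = 0, u_OE = 0)
  .protocol(rbind(seg, tail_seg),
            sprintf("bat:block=%g,t0=%g,n=%d", block, tStart, nCycles))
}

#' Protocol lookup and segments
#'
#' \code{protocolValue} evaluates the treatment signals at time(s) \code{t}
#' by binary search over segment starts (O(log n) per query);
#' \code{protocolSegments} returns the segment table.
#'
#' @param protocol a [Protocol-class] object.
#' @param t time or vector of times (h) within the protocol span.
#' @return \code{protocolValue}: for scalar \code{t} a named numeric
#'   \code{c(u_ADT, u_OE)}; for vector \code{t} a two-column matrix.
#' @export
protocolValue <- function(protocol, t) {
  stopifnot(is(protocol, "Protocol"))
  s <- protocol@segments
  if (any(t < s$t_start[1L] | t >= s$t_end[nrow(s)] + 1e-9))
    stop("time outside the protocol span")
  idx <- findInterval(t, s$t_start)  # left-closed, right-open
  m <- cbind(u_ADT = s$u_ADT[idx], u_OE = s$u_OE[idx])
  if (length(t) == 1L)
    c(u_ADT = unname(m[1L, 1L]), u_OE = unname(m[1L, 2L]))
  else m
}

#' @rdname protocolValue
#' @export
protocolSegments <- function(protocol) {
  stopifnot(is(protocol, "Protocol"))
  protocol@segments
}

#' Parse a protocol shortcut string
#'
#' Command-line style shortcuts: \code{"none"}, \code{"adt:t_on=500,u=1"},
#' \code{"iadt:on=168,off=168,t0=0,n=5"}, \code{"bat:block=336,t0=0,n=3"}.
#' Omitted fields take the constructor defaults.
#'
#' @param spec shortcut string.
#' @return a [Protocol-class] object.
#' @export
parseProtocolSpec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  kind <- parts[1L]
  kv <- list()
  if (length(parts) > 1L) {
    for (item in strsplit(parts[2L], ",", fixed = TRUE)[[1L]]) {
      p <- strsplit(item, "=", fixed = TRUE)[[1L]]
      if (length(p) != 2L) stop("malformed protocol spec: ", spec)
      kv[[p[1L]]] <- as.numeric(p[2L])
    }
  }
  g <- function(nm, default) if (!is.null(kv[[nm]])) kv[[nm]] else default
  switch(kind,
    none = noTreatment(),
    adt = constantADT(tOn = g("t_on", 0), u = g("u", 1)),
    iadt = intermittentADT(onDuration = g("on", 168),
                           offDuration = g("off", 168),
                           tStart = g("t0", 0),
                           nCycles = as.integer(g("n", 5))),
    bat = batProtocol(block = g("block", 336), tStart = g("t0", 0),
                      nCycles = as.integer(g("n", 3))),
    stop("unknown protocol kind: ", kind))
}
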