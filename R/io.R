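# md5-based short hash of a character scalar (provenance tags, config hashes)
.shortHash <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  substr(unname(tools::md5sum(tf)), 1L, 8L)
}

.pkgVersion <- function() {
  as.character(utils::packageVersion("page4dyn"))
}

# comment header recording provenance: package version, seed, config hash
.fileHeader <- function(seed = NA, config = "") {
  c(sprintf("# page4dyn %s", .pkgVersion()),
    sprintf("# seed: %s", ifelse(is.na(seed), "NA", as.character(seed))),
    sprintf("# config_hash: %s", .shortHash(paste0(config, collapse = "|"))))
}

#' Read and write circuit parameter files
#'
#' Flat YAML with keys matching the [CircuitParams-class] field names.
#' The calibrated default ships as \code{inst/params/default.yaml}.
#'
#' @param params a [CircuitParams-class] object.
#' @param path file path.
#' @param seed seed recorded in the file header (optional).
#' @return \code{readCircuitParams}: a [CircuitParams-class] object.
#' @export
writeCircuitParams <- function(params, path, seed = NA) {
  stopifnot(is(params, "CircuitParams"))
  v <- paramsVector(params)
  txt <- yaml::as.yaml(as.list(v), precision = 15)
  writeLines(c(.fileHeader(seed, txt), txt), path)
  invisible(path)
}

#' @rdname writeCircuitParams
#' @export
readCircuitParams <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  v <- yaml::read_yaml(path)
  missing <- setdiff(.circuitParamNames, names(v))
  if (length(missing))
    stop("parameter file lacks keys: ", paste(missing, collapse = ", "))
  .paramsFromVector(unlist(v[.circuitParamNames]))
}

#' Read and write protocol files
#'
#' YAML with a \code{label} and a list of segments
#' (\code{t_start}, \code{t_end}, \code{u_ADT}, \code{u_OE}); an unbounded
#' final segment is stored as \code{.inf}. Round-trips exactly.
#'
#' @param protocol a [Protocol-class] object.
#' @param path file path.
#' @param seed seed recorded in the header (optional).
#' @return \code{readProtocol}: a [Protocol-class] object.
#' @export
writeProtocol <- function(protocol, path, seed = NA) {
  stopifnot(is(protocol, "Protocol"))
  s <- protocol@segments
  obj <- list(label = protocol@label,
              segments = lapply(seq_len(nrow(s)), function(k)
                as.list(s[k, c("t_start", "t_end", "u_ADT", "u_OE")])))
  txt <- yaml::as.yaml(obj, precision = 15)
  writeLines(c(.fileHeader(seed, txt), txt), path)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  obj <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(obj$segments, function(x)
    data.frame(t_start = x$t_start, t_end = x$t_end, u_ADT = x$u_ADT,
               u_OE = x$u_OE)))
  .protocol(seg, obj$label)
}

#' Read and write trajectory CSV files
#'
#' CSV with columns \code{time_h, W, H, C, K, A} preceded by a comment
#' header (\code{#} lines: package version, seed, config hash).
#'
#' @param traj a [Trajectory-class] object.
#' @param path file path.
#' @param seed seed recorded in the header (optional).
#' @return \code{readTrajectoryCSV}: a [Trajectory-class] object.
#' @export
writeTrajectoryCSV <- function(traj, path, seed = NA) {
  stopifnot(is(traj, "Trajectory"))
  df <- data.frame(time_h = traj@times, traj@states, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.fileHeader(seed, paste(traj@paramsId, traj@protocolId)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  states <- as.matrix(df[, .species])
  new("Trajectory", times = df$time_h, states = states,
      paramsId = "file", protocolId = "file")
}

#' Write a contact map as TSV
#'
#' Tab-separated L x L probability matrix with a comment header.
#'
#' @param cm a [ContactMap-class] object.
#' @param path file path.
#' @param seed seed recorded in the header (optional).
#' @export
writeContactMapTSV <- function(cm, path, seed = NA) {
  stopifnot(is(cm, "ContactMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.fileHeader(seed, sprintf("cutoff=%g,minSeqSep=%g", cm@cutoff,
                                       cm@minSeqSep)), con)
  utils::write.table(cm@map, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write contact-PCA modes as JSON
#'
#' One record per retained residue pair: \code{{"pair": [i, j], "pc1": ...,
#' "pc2": ...}}, with provenance under \code{"_meta"}.
#'
#' @param pca a [ContactPCA-class] object.
#' @param path file path.
#' @param seed seed recorded in the metadata (optional).
#' @export
writePCAJSON <- function(pca, path, seed = NA) {
  stopifnot(is(pca, "ContactPCA"))
  recs <- lapply(seq_len(nrow(pca@pairIndex)), function(r) {
    rec <- list(pair = c(pca@pairIndex$i[r], pca@pairIndex$j[r]))
    for (m in seq_len(ncol(pca@modes)))
      rec[[sprintf("pc%d", m)]] <- pca@modes[r, m]
    rec
  })
  obj <- list(
    `_meta` = list(package = sprintf("page4dyn %s", .pkgVersion()),
                   seed = if (is.na(seed)) NULL else seed,
                   eigenvalues = pca@eigenvalues),
    modes = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write multi-model XYZ ensembles
#'
#' One block per conformer: an atom-count line, a comment line
#' (\code{model k}), then one \code{CA x y z} row per residue
#' (coordinates in Angstrom, printed to 3 decimals).
#'
#' @param ensemble an [Ensemble-class] object.
#' @param path file path.
#' @return \code{readEnsembleXYZ}: an [Ensemble-class] object.
#' @export
writeEnsembleXYZ <- function(ensemble, path) {
  stopifnot(is(ensemble, "Ensemble"))
  n <- nConformers(ensemble)
  L <- chainLength(ensemble)
  out <- character(n * (L + 2L))
  pos <- 1L
  for (k in seq_len(n)) {
    xyz <- conformer(ensemble, k)
    out[pos] <- as.character(L)
    out[pos + 1L] <- sprintf("model %d", k)
    out[pos + 1L + seq_len(L)] <-
      sprintf("CA %.3f %.3f %.3f", xyz[, 1L], xyz[, 2L], xyz[, 3L])
    pos <- pos + L + 2L
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname writeEnsembleXYZ
#' @export
readEnsembleXYZ <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  pos <- 1L
  confs <- list()
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    L <- as.integer(trimws(lines[pos]))
    if (is.na(L)) stop("malformed XYZ: expected atom count at line ", pos)
    block <- lines[pos + 1L + seq_len(L)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p)
      as.numeric(p[(length(p) - 2L):length(p)]), numeric(3)))
    confs[[length(confs) + 1L]] <- xyz
    pos <- pos + L + 2L
  }
  n <- length(confs)
  L <- nrow(confs[[1L]])
  coords <- array(NA_real_, dim = c(n, L, 3L))
  for (k in seq_len(n)) coords[k, , ] <- confs[[k]]
  new("Ensemble", coords = coords, labels = character(0))
}

#' Read and write C-alpha-only multi-MODEL PDB ensembles
#'
#' Reading uses \pkg{bio3d} (multi-model PDB parsing, C-alpha selection);
#' writing emits minimal \code{MODEL}/\code{ATOM}/\code{ENDMDL} records
#' with residue numbers 1..L.
#'
#' @param ensemble an [Ensemble-class] object.
#' @param path file path.
#' @return \code{readEnsemblePDB}: an [Ensemble-class] object.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  stopifnot(is(ensemble, "Ensemble"))
  n <- nConformers(ensemble)
  L <- chainLength(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n)) {
    xyz <- conformer(ensemble, k)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(L), seq_len(L), xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname writeEnsemblePDB
#' @export
readEnsemblePDB <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB ensembles requires the 'bio3d' package")
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  n <- nrow(xyz)
  L <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(n, L, 3L))
  for (k in seq_len(n))
    coords[k, , ] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
  new("Ensemble", coords = coords, labels = character(0))
}
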