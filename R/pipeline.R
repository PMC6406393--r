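#' Anti-correlation of loop modes in a contact PCA
#'
#' Sums the first principal mode's coefficients over the N-loop block
#' (N-motif 4-12 against the central acidic region 43-62) and over the
#' C-loop block (central acidic region against the C-motif 82-95). Opposite
#' signs of the two sums indicate mutually exclusive (anti-correlated) loop
#' formation, the signature of the HIPK1 form.
#'
#' @param pca a [ContactPCA-class] object.
#' @param mode which mode to inspect (default 1).
#' @return list with \code{nSum}, \code{cSum} and logical
#'   \code{anticorrelated}.
#' @export
loopAnticorrelation <- function(pca, mode = 1L) {
  stopifnot(is(pca, "ContactPCA"))
  reg <- pageRegions()
  v <- pca@modes[, mode]
  inN <- pca@pairIndex$i %in% reg$n_motif &
    pca@pairIndex$j %in% reg$central_acidic
  inC <- pca@pairIndex$i %in% reg$central_acidic &
    pca@pairIndex$j %in% reg$c_motif
  nSum <- sum(v[inN])
  cSum <- sum(v[inC])
  list(nSum = nSum, cSum = cSum,
       anticorrelated = is.finite(nSum * cSum) && nSum * cSum < 0)
}

#' Pipeline run configuration
#'
#' @param paramsFile path to a parameter YAML, or \code{NULL} for the
#'   calibrated default.
#' @param protocolSpec protocol shortcut string (see [parseProtocolSpec()]).
#' @param seed integer seed used for every stochastic stage.
#' @param outputDir directory for the report bundle (created if needed).
#' @param nCells cohort size.
#' @param nConformers conformers per synthetic preset.
#' @param tEnd single-cell simulation end time (h).
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(paramsFile = NULL, protocolSpec = "adt:t_on=1000",
                      seed = 42L, outputDir = tempfile("page4dyn_run_"),
                      nCells = 200L, nConformers = 150L, tEnd = 6000,
                      logLevel = c("info", "quiet")) {
  if (!is.null(paramsFile) && !file.exists(paramsFile))
    stop("parameter file not found: ", paramsFile)
  structure(list(paramsFile = paramsFile, protocolSpec = protocolSpec,
                 seed = as.integer(seed), outputDir = outputDir,
                 nCells = as.integer(nCells),
                 nConformers = as.integer(nConformers), tEnd = tEnd,
                 logLevel = match.arg(logLevel)),
            class = "RunConfig")
}

.stage <- function(name, config, expr) {
  if (config$logLevel == "info")
    message(sprintf("[page4dyn] stage: %s", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes parameter loading, a single-cell simulation under the configured
#' protocol, oscillation and quench analysis, cohort snapshots at days
#' 0/7/14 under constant ADT, protocol comparisons (intermittent ADT
#' synchronization, BAT phenotype alternation), synthetic ensembles for the
#' three presets, and the structural metrics. Writes CSV/TSV/JSON artifacts
#' plus a machine-readable \code{summary.json} into the output directory and
#' returns the summary invisibly. Outputs carry comment headers with the
#' package version, seed and config hash. Reruns with the same config are
#' identical.
#'
#' @param config a [runConfig()] list.
#' @return invisibly, the named summary list (keys include
#'   \code{period_h}, \code{quench_h}, \code{cv_day0}, \code{cv_day14},
#'   \code{rg_ordering_ok}, \code{pca_anticorrelation_ok}).
#' @export
runFullPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- function(f) file.path(config$outputDir, f)

  params <- .stage("load-params", config, {
    if (is.null(config$paramsFile)) defaultCircuitParams()
    else readCircuitParams(config$paramsFile)
  })

  protocol <- .stage("protocol", config, parseProtocolSpec(config$protocolSpec))

  traj <- .stage("simulate", config, {
    tr <- simulateCircuit(params, protocol, .canonicalInit(),
                          c(0, config$tEnd))
    writeTrajectoryCSV(tr, out("trajectory.csv"), seed)
    tr
  })

  osc <- .stage("oscillation", config, {
    trFree <- simulateCircuit(params, noTreatment(), .canonicalInit(),
                              c(0, config$tEnd))
    detectPeriod(trFree, "H", burnIn = min(2000, config$tEnd / 3))
  })

  quench <- .stage("quench", config, {
    tOn <- 1000
    trQ <- simulateCircuit(params, constantADT(tOn), .canonicalInit(),
                           c(0, tOn + 1500))
    quenchTime(trQ, "H", tOn = tOn, burnIn = 200)
  })

  cohortStats <- .stage("cohort", config, {
    ch <- simulateCohort(params, constantADT(0), config$nCells, seed,
                         tSpan = c(0, 14 * 24))
    days <- c(0, 7, 14)
    snap <- do.call(rbind, lapply(days, function(d) {
      i <- .cohortTimeIndex(ch, d * 24)
      st <- ch@states[, i, ]
      data.frame(cell_id = seq_len(ch@nCells), day = d, st,
                 phenotype = classifyPhenotype(st, ch@cycleMid[["h_mid"]],
                                               ch@cycleMid[["c_mid"]]))
    }))
    con <- file(out("cohort_snapshots.csv"), "w")
    writeLines(.fileHeader(seed, config$protocolSpec), con)
    utils::write.csv(snap, con, row.names = FALSE, quote = FALSE)
    close(con)
    list(cv0 = populationCV(ch, "K", 0), cv14 = populationCV(ch, "K", 336))
  })

  syncIADT <- .stage("intermittent-adt", config, {
    ch <- simulateCohort(params, intermittentADT(168, 168, 0, 2L),
                         max(20L, config$nCells %/% 10L), seed + 1L,
                         tSpan = c(0, 672))
    syncOrderParameter(ch, 672)
  })

  bat <- .stage("bat", config, {
    ch <- simulateCohort(params, batProtocol(336, 0, 2L),
                         max(20L, config$nCells %/% 10L), seed + 2L,
                         tSpan = c(0, 1344))
    list(oe = phenotypeFractions(ch, 330),   # end of first OE block
         adt = phenotypeFractions(ch, 672))  # end of first ADT block
  })

  ensStats <- .stage("ensembles", config, {
    presets <- defaultPresets()
    rgMean <- numeric(0)
    pcaH <- NULL
    blockP <- numeric(0)
    reg <- pageRegions()
    for (nm in names(presets)) {
      ens <- generateEnsemble(presets[[nm]], config$nConformers,
                              seed + match(nm, names(presets)))
      writeEnsembleXYZ(ens, out(sprintf("ensemble_%s.xyz", nm)))
      rg <- radiusOfGyration(ens)
      rgMean[nm] <- mean(rg)
      prof <- freeEnergyProfile(rg, nBins = 30, allowSmall = TRUE)
      utils::write.csv(prof, out(sprintf("rg_profile_%s.csv", nm)),
                       row.names = FALSE)
      cm <- contactMap(ens)
      writeContactMapTSV(cm, out(sprintf("contact_map_%s.tsv", nm)), seed)
      blockP[nm] <- blockContactProbability(cm, reg$n_motif,
                                            reg$central_acidic)
      pca <- contactPCA(ens)
      writePCAJSON(pca, out(sprintf("contact_pca_%s.json", nm)), seed)
      if (nm == "HIPK1") pcaH <- pca
    }
    list(rgMean = rgMean, blockP = blockP,
         anti = loopAnticorrelation(pcaH))
  })

  summary <- list(
    period_h = osc@period,
    quench_h = quench - 1000,
    cv_day0 = cohortStats$cv0,
    cv_day14 = cohortStats$cv14,
    sync_iadt = syncIADT,
    bat_ad_frac_oe = unname(bat$oe[["AD"]]),
    bat_ai_frac_adt = unname(bat$adt[["AI"]]),
    nloop_block_wt = unname(ensStats$blockP[["WT"]]),
    nloop_block_clk2 = unname(ensStats$blockP[["CLK2"]]),
    rg_wt = unname(ensStats$rgMean[["WT"]]),
    rg_hipk1 = unname(ensStats$rgMean[["HIPK1"]]),
    rg_clk2 = unname(ensStats$rgMean[["CLK2"]]),
    rg_ordering_ok =
      ensStats$rgMean[["CLK2"]] > ensStats$rgMean[["WT"]] &&
      abs(ensStats$rgMean[["WT"]] - ensStats$rgMean[["HIPK1"]]) /
        ensStats$rgMean[["WT"]] < 0.10,
    pca_anticorrelation_ok = ensStats$anti$anticorrelated,
    seed = seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}
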