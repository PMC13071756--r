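# End-to-end orchestration: filter -> thin -> select predictors ->
# tune/fit -> threshold -> simulate (limited + unlimited, each scenario)
# -> range dynamics, with a single master seed fanned out into named
# child streams and a manifest hashing every written artifact.

#' Assemble a pipeline run configuration
#'
#' The default configuration is the self-contained synthetic demo: a
#' 50 x 50 grid, two forcing scenarios, one virtual species sampled from
#' the moderate-forcing stack, and a simulation horizon of 2025--2100.
#'
#' @param profile A \linkS4class{SpeciesProfile} for the simulated
#'   species.
#' @param climateParams \code{\link{syntheticClimateParams}} driving stack
#'   generation (synthetic mode), or \code{NULL} when \code{stacks} are
#'   supplied directly.
#' @param stacks Optional named list of pre-built
#'   \linkS4class{ClimateStack} per scenario.
#' @param virtual A \linkS4class{VirtualSpecies} to sample occurrences
#'   from (synthetic mode), or \code{NULL} when \code{occurrences} are
#'   supplied.
#' @param occurrences Optional raw occurrence data frame.
#' @param nOccurrences Number of raw records to synthesize (default 400).
#' @param positionalErrorKm Occurrence coordinate jitter SD (default 2).
#' @param scenarios Scenario names to simulate.
#' @param years Simulation years (default 2025:2100).
#' @param currentRange Current-climate period (default 2000--2024).
#' @param filterRules \code{\link{occurrenceFilterRules}}.
#' @param priority Predictor priority ordering (default temperature and
#'   precipitation first; see \code{\link{selectPredictors}}).
#' @param fcGrid,rmGrid Tuning grid (defaults: all 7 feature classes, RM
#'   1 to 3 by 0.5). Pass single values to skip tuning.
#' @param elevation Optional elevation \linkS4class{RasterLayer}.
#' @param masterSeed Master integer seed.
#' @param outDir Optional output directory for the artifact tree.
#' @return List of class \code{"RunConfig"}.
#' @export
runConfig <- function(profile = speciesProfile("virtual_species", 12,
                                               taxon = "bird"),
                      climateParams = syntheticClimateParams(),
                      stacks = NULL,
                      virtual = virtualSpecies(
                        c(bio01 = 12.5, bio12 = 960, bio04 = 645),
                        c(bio01 = 0.8, bio12 = 45, bio04 = 25)),
                      occurrences = NULL, nOccurrences = 400,
                      positionalErrorKm = 2,
                      scenarios = c("RCP4.5-like", "RCP8.5-like"),
                      years = 2025:2100, currentRange = c(2000, 2024),
                      filterRules = occurrenceFilterRules(),
                      priority = NULL,
                      fcGrid = c("L", "Q", "LQ", "LQP"),
                      rmGrid = c(1, 2, 3),
                      elevation = NULL, masterSeed = 1L, outDir = NULL) {
  if (is.null(stacks) && is.null(climateParams))
    .stopf("either climateParams (synthetic mode) or stacks must be given")
  structure(list(profile = profile, climateParams = climateParams,
                 stacks = stacks, virtual = virtual,
                 occurrences = occurrences, nOccurrences = nOccurrences,
                 positionalErrorKm = positionalErrorKm,
                 scenarios = scenarios, years = as.integer(years),
                 currentRange = currentRange, filterRules = filterRules,
                 priority = priority, fcGrid = fcGrid, rmGrid = rmGrid,
                 elevation = elevation, masterSeed = as.integer(masterSeed),
                 outDir = outDir),
            class = "RunConfig")
}

#' Run the full pipeline for one species
#'
#' Executes every stage on the configured inputs and returns all
#' intermediate and final artifacts. Reruns with the same configuration
#' and master seed reproduce every output (including written files)
#' bit-identically; the unlimited-dispersal runs consume no random
#' numbers.
#'
#' @param config A \code{\link{runConfig}} list.
#' @param quiet Suppress per-stage messages (default TRUE).
#' @return List of class \code{"SpeciesRunResult"} with elements
#'   \code{stacks}, \code{occurrencesRaw}, \code{occurrences} (thinned
#'   \linkS4class{OccurrenceSet}), \code{selection}, \code{model},
#'   \code{threshold} (the \code{\link{optimalThreshold}} result),
#'   \code{evaluation} (partial-ROC summary), \code{runs} (per scenario:
#'   limited and unlimited \linkS4class{DispersalRun}), \code{series}
#'   (per scenario \linkS4class{ScenarioSeries}), and \code{manifest}.
#' @export
runSpecies <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  seed <- config$masterSeed
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  profile <- config$profile

  # --- climate stacks -------------------------------------------------
  stacks <- config$stacks
  if (is.null(stacks)) {
    stacks <- lapply(config$scenarios, function(sc)
      makeClimateStack(config$climateParams, sc,
                       seed = deriveSeed(seed, "climate")))
    names(stacks) <- config$scenarios
  }
  baseStack <- stacks[[1]]
  say("stacks ready: %s", paste(names(stacks), collapse = ", "))

  # --- occurrences ----------------------------------------------------
  raw <- config$occurrences
  if (is.null(raw)) {
    raw <- sampleOccurrences(config$virtual, baseStack,
                             n = config$nOccurrences,
                             positionalErrorKm = config$positionalErrorKm,
                             yearRange = config$currentRange,
                             seed = deriveSeed(seed, "occurrences"),
                             speciesId = profile@speciesId,
                             pOldYear = 0.05, pMissingCoord = 0.02)
  }
  filtered <- filterRecords(raw, config$filterRules)
  thinned <- thinToGrid(filtered, baseStack@grid)
  say("occurrences: %d raw -> %d filtered -> %d thinned",
      nrow(raw), length(filtered), length(thinned))
  if (length(thinned) < 8)
    .stopf("stage occurrences: only %d thinned presences", length(thinned))

  # --- predictors -----------------------------------------------------
  meanLayers <- temporalMean(baseStack, config$currentRange)
  selection <- selectPredictors(meanLayers, priority = config$priority)
  vars <- selection$selected
  say("predictors: %s", paste(vars, collapse = ", "))

  # --- model ----------------------------------------------------------
  presCells <- thinned@records$cell
  envAt <- function(cells) {
    m <- vapply(vars, function(v) as.vector(meanLayers[[v]]@values)[cells],
                numeric(length(cells)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, vars))
    m
  }
  bgCells <- sampleBackground(baseStack@mask, length(vars),
                              seed = deriveSeed(seed, "background"))
  presEnv <- envAt(presCells)
  bgEnv <- envAt(bgCells)
  coords <- as.matrix(thinned@records[, c("decimalLongitude",
                                          "decimalLatitude")])
  model <- tuneModel(presEnv, bgEnv, fcGrid = config$fcGrid,
                     rmGrid = config$rmGrid, presCoords = coords)
  say("model: FC=%s RM=%.1f AICc=%.2f", model@fc, model@rm,
      model@report$AICc)

  # --- threshold + evaluation ----------------------------------------
  current <- projectSuitability(model, meanLayers, config$elevation,
                                profile@elevationBound)
  presSuit <- as.vector(current@values)[presCells]
  bgSuit <- as.vector(current@values)[bgCells]
  threshold <- optimalThreshold(presSuit, bgSuit)
  pauc <- partialAucRatio(current, coords,
                          seed = deriveSeed(seed, "pauc"))
  say("threshold tau=%.3f TSS=%.3f Kappa=%.3f pAUC=%.3f",
      threshold$tau, threshold$tss, threshold$kappa, pauc$meanRatio)

  # --- simulation -----------------------------------------------------
  runs <- list(); series <- list()
  for (sc in config$scenarios) {
    lim <- runDispersal(profile, thinned, model, stacks[[sc]],
                        tau = threshold$tau, years = config$years,
                        mode = "limited", elevation = config$elevation,
                        currentRange = config$currentRange,
                        seed = deriveSeed(seed, "kernel", profile@speciesId,
                                          sc, "limited"))
    unl <- runDispersal(profile, thinned, model, stacks[[sc]],
                        tau = threshold$tau, years = config$years,
                        mode = "unlimited", elevation = config$elevation,
                        currentRange = config$currentRange)
    runs[[sc]] <- list(limited = lim, unlimited = unl)
    series[[sc]] <- scenarioSeries(lim, unl)
    say("scenario %s: proportion %s", sc, series[[sc]]@proportionClass)
  }

  result <- structure(
    list(config = config, stacks = stacks, occurrencesRaw = raw,
         occurrences = thinned, selection = selection, model = model,
         threshold = threshold, evaluation = pauc, runs = runs,
         series = series, manifest = NULL),
    class = "SpeciesRunResult")
  if (!is.null(config$outDir))
    result$manifest <- writeRunArtifacts(result, config$outDir)
  result
}

#' @export
print.SpeciesRunResult <- function(x, ...) {
  cat(sprintf("SpeciesRunResult '%s': %d presences, model FC=%s RM=%.1f, tau=%.3f\n",
              x$config$profile@speciesId, length(x$occurrences),
              x$model@fc, x$model@rm, x$threshold$tau))
  for (sc in names(x$series)) show(x$series[[sc]])
  invisible(x)
}

#' Write the artifact tree of a pipeline run
#'
#' Writes occurrence CSVs, the model JSON, the per-scenario results table
#' and summary, and a manifest listing every output file with its MD5
#' content hash plus the seeds and stage record counts.
#'
#' @param result A \code{\link{runSpecies}} result.
#' @param outDir Output directory (created if needed).
#' @return The manifest list, invisibly written to
#'   \code{manifest.json}.
#' @export
writeRunArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  files <- character()
  put <- function(f) { files <<- c(files, f); f }

  writeOccurrences(result$occurrencesRaw,
                   put(file.path(outDir, "occurrences_raw.csv")))
  writeOccurrences(result$occurrences,
                   put(file.path(outDir, "occurrences_thinned.csv")))
  writeNicheModel(result$model, put(file.path(outDir, "model.json")))

  tabs <- do.call(rbind, lapply(result$series, as.data.frame))
  utils::write.csv(tabs, put(file.path(outDir, "area_series.csv")),
                   row.names = FALSE, quote = FALSE)
  for (sc in names(result$runs)) {
    for (mode in c("limited", "unlimited")) {
      run <- result$runs[[sc]][[mode]]
      lastYear <- max(run@years)
      lay <- RasterLayer(run@grid,
                         run@occupied[[as.character(lastYear)]] * 1)
      writeAsciiGrid(lay, put(file.path(outDir,
        sprintf("occupied_%s_%s_%d.asc", gsub("[^A-Za-z0-9.-]", "_", sc),
                mode, lastYear))))
    }
  }
  summary <- list(
    speciesId = cfg$profile@speciesId,
    threshold = result$threshold[c("tau", "tss", "kappa")],
    pAUC = result$evaluation$meanRatio,
    selected = result$selection$selected,
    series = lapply(result$series, function(s)
      list(scenario = s@scenario, trendLimited = s@trendLimited,
           trendUnlimited = s@trendUnlimited,
           proportionClass = s@proportionClass,
           finalProportion = s@proportion[length(s@proportion)])))
  jsonlite::write_json(summary, put(file.path(outDir, "summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    speciesId = cfg$profile@speciesId,
    masterSeed = cfg$masterSeed,
    scenarios = cfg$scenarios,
    years = range(cfg$years),
    counts = list(raw = nrow(result$occurrencesRaw),
                  thinned = length(result$occurrences)),
    model = list(fc = result$model@fc, rm = result$model@rm,
                 AICc = result$model@report$AICc),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
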