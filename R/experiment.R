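## Experiment workbench: run the headline in-silico comparisons (control vs
## PAR1-activated scenes, different transporter densities) from one YAML
## configuration, with full provenance, and render human-readable reports.

experimentConfigKeys <- list(
  top = c("name", "seeds", "simulation", "kinetics", "conditions", "edge"),
  condition = c("name", "scene", "overrides"),
  kinetics = c("applyQ10", "kOn", "kOff", "kTrans", "kReorient", "km",
               "q10", "tRef", "tSim"))

validateExperimentConfig <- function(cfg) {
  bad <- setdiff(names(cfg), experimentConfigKeys$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop("config must list at least one condition")
  for (cond in cfg$conditions) {
    bad <- setdiff(names(cond), experimentConfigKeys$condition)
    if (length(bad))
      stop("unknown condition key(s): ", paste(bad, collapse = ", "))
    if (is.null(cond$name) || is.null(cond$scene))
      stop("each condition needs a name and a scene preset")
  }
  if (!is.null(cfg$kinetics)) {
    bad <- setdiff(names(cfg$kinetics), experimentConfigKeys$kinetics)
    if (length(bad))
      stop("unknown kinetics key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$simulation)) {
    bad <- setdiff(names(cfg$simulation), slotNames("SimConfig"))
    if (length(bad))
      stop("unknown simulation key(s): ", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Run a configured in-silico experiment
#'
#' Executes scene building, multi-seed Monte Carlo simulation and seed
#' aggregation for every condition in the configuration, writes per-condition
#' time-series CSVs plus a summary table, and returns a manifest with full
#' provenance (config snapshot, seeds, config hashes, output paths).
#'
#' The YAML configuration has keys \code{name}, \code{seeds} (a count or a
#' two-element range), optional \code{simulation} (SimConfig fields),
#' optional \code{kinetics} (transporter parameters and \code{applyQ10}),
#' and \code{conditions}: a list of \code{name}/\code{scene} (a
#' \code{\link{sceneSpec}} preset) with optional \code{overrides} of
#' SceneSpec fields.
#'
#' @param config path to a YAML file, or an equivalent list.
#' @param outDir output directory (created if needed).
#' @param verbose log per-stage progress to stderr.
#' @return The manifest (a list), invisibly also written to
#'   \code{manifest.json} in \code{outDir}.
#' @export
runExperiment <- function(config, outDir = tempfile("experiment"),
                          verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validateExperimentConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  seeds <- config$seeds
  seeds <- if (is.null(seeds)) 1:30
           else if (length(seeds) == 1L) seq_len(seeds)
           else seq(seeds[[1L]], seeds[[2L]])
  kin <- config$kinetics
  applyQ10 <- !identical(kin$applyQ10, FALSE)
  kin$applyQ10 <- NULL
  params <- do.call(transporterParams, kin %||% list())
  scheme <- transporterScheme(params, applyQ10 = applyQ10)
  simCfg <- do.call(simConfig, config$simulation %||% list())
  edge <- config$edge %||% 0.02

  summary <- NULL
  outputs <- list()
  for (cond in config$conditions) {
    t0 <- Sys.time()
    say("[%s] building scene '%s'", cond$name, cond$scene)
    spec <- do.call(sceneSpec, c(list(condition = cond$scene),
                                 cond$overrides %||% list()))
    scene <- buildScene(spec, edge = edge)
    say("[%s] simulating %d seeds", cond$name, length(seeds))
    res <- tryCatch(
      runSeeds(scene, list(GLT = scheme), simCfg, seeds = seeds),
      error = function(e) stop("stage 'simulate' failed for condition '",
                               cond$name, "': ", conditionMessage(e)))
    agg <- aggregateSeeds(res)
    perSeed <- data.frame(
      seed = seeds,
      cleftCentroid = vapply(res, countCentroid, 0, series = "freeCleft"),
      extraCentroid = vapply(res, countCentroid, 0, series = "freeExtra"))
    tsPath <- file.path(outDir, paste0(cond$name, "_timeseries.csv"))
    write.csv(cbind(time_ms = agg@time,
                    setNames(agg@mean, paste0("mean_", names(agg@mean))),
                    setNames(agg@sem, paste0("sem_", names(agg@sem)))),
              tsPath, row.names = FALSE)
    seedPath <- file.path(outDir, paste0(cond$name, "_centroids.csv"))
    write.csv(perSeed, seedPath, row.names = FALSE)
    last <- nrow(agg@mean)
    summary <- rbind(summary, data.frame(
      condition = cond$name,
      nSeeds = length(seeds),
      cleftCentroidMs = mean(perSeed$cleftCentroid),
      cleftCentroidSem = sd(perSeed$cleftCentroid) / sqrt(nrow(perSeed)),
      extraCentroidMs = mean(perSeed$extraCentroid),
      extraCentroidSem = sd(perSeed$extraCentroid) / sqrt(nrow(perSeed)),
      bindings = agg@mean$binding[last],
      unbindings = agg@mean$unbinding[last],
      translocations = agg@mean$translocation[last],
      astroAreaUm2 = sceneAstroArea(scene),
      transporters = sum(vapply(scene@populations,
                                function(p) nrow(p@positions), 0L))))
    outputs[[cond$name]] <- list(
      timeseries = tsPath, centroids = seedPath,
      configHash = res[[1L]]@configHash,
      elapsedS = as.numeric(Sys.time() - t0, units = "secs"))
    say("[%s] done in %.1f s", cond$name, outputs[[cond$name]]$elapsedS)
  }
  sumPath <- file.path(outDir, "summary.csv")
  write.csv(summary, sumPath, row.names = FALSE)
  manifest <- list(
    name = config$name %||% "experiment",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = as.character(utils::packageVersion("GluClear")),
    config = config, seeds = seeds, outDir = outDir,
    summary = sumPath, outputs = outputs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a human-readable experiment report
#'
#' One table per figure analogue: per-condition clearance centroids (cleft
#' and neuropil) and cumulative transporter reaction totals, each traceable
#' to the manifest's output files and config hashes.
#'
#' @param manifest a manifest list from \code{\link{runExperiment}}, or the
#'   path to a \code{manifest.json}.
#' @param file output file; \code{""} prints to the console.
#' @return The report lines, invisibly.
#' @export
writeReport <- function(manifest, file = "") {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  lines <- c(sprintf("Experiment report: %s", manifest$name),
             sprintf("created %s, package GluClear %s", manifest$created,
                     manifest$package), "")
  if (is.null(manifest$summary) || !file.exists(manifest$summary)) {
    warning("manifest lists no readable summary; empty report")
    lines <- c(lines, "(no outputs)")
    writeLines(lines, file)
    return(invisible(lines))
  }
  s <- read.csv(manifest$summary)
  lines <- c(lines, "Glutamate lifetime (count centroids, mean +/- SEM):")
  for (i in seq_len(nrow(s)))
    lines <- c(lines, sprintf(
      "  %-22s cleft %6.3f +/- %.3f ms   neuropil %6.3f +/- %.3f ms (n=%d)",
      s$condition[i], s$cleftCentroidMs[i], s$cleftCentroidSem[i],
      s$extraCentroidMs[i], s$extraCentroidSem[i], s$nSeeds[i]))
  lines <- c(lines, "", "Cumulative transporter reactions (mean per seed):")
  for (i in seq_len(nrow(s)))
    lines <- c(lines, sprintf(
      "  %-22s binding %8.1f  unbinding %7.1f  translocation %8.1f",
      s$condition[i], s$bindings[i], s$unbindings[i], s$translocations[i]))
  lines <- c(lines, "", "Scenes:")
  for (i in seq_len(nrow(s)))
    lines <- c(lines, sprintf(
      "  %-22s astrocytic area %.3f um^2, %d transporters",
      s$condition[i], s$astroAreaUm2[i], s$transporters[i]))
  lines <- c(lines, "", "Outputs:")
  for (nm in names(manifest$outputs)) {
    o <- manifest$outputs[[nm]]
    lines <- c(lines, sprintf("  %s: %s (config %s)", nm, o$timeseries,
                              substr(o$configHash, 1, 8)))
  }
  writeLines(lines, file)
  invisible(lines)
}
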