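# Pipeline orchestration: generate -> (preprocess -> spectra) -> reliability
# -> models, from a validated config, with deterministic seeding and
# TSV/JSON outputs.

configDefaults <- function() list(
  mode = "tabular",                  # "tabular" or "waveform"
  seed = 20260927L,
  cohort = list(nAbstinent = 15, nNonAbstinent = 17),
  gen = list(),                      # overrides for genParams()
  waveform = list(durationS = 90, srate = 500),
  preprocessing = list(absThresholdUv = 100, stepThresholdUv = 50,
                       channelFrac = 0.40, segmentFrac = 0.10,
                       neighbors = 4),
  spectral = list(taperFraction = 0.10, band = c(8, 13),
                  epochAverage = "power", floorEps = NULL),
  reliability = list(threshold = 0.7),
  models = c(1, 2, 3, 4, 5, 6, 7),
  mcmc = list(chains = 4, iterations = 2000, warmup = 1000))

#' Build and validate a pipeline configuration
#'
#' Starts from the defaults (15 + 17 participants, default montage and
#' generative parameters, models 1-7, 4 x 2000 MCMC iterations with 1000
#' warmup) and applies overrides. Unknown keys are rejected.
#'
#' @param ... overrides, e.g. \code{mode = "tabular"},
#'   \code{models = 3}, \code{mcmc = list(chains = 2)}
#' @return validated config list
#' @export
pipelineConfig <- function(...) {
  cfg <- configDefaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stopLabeled("config", "unknown config key(s): ",
                paste(bad, collapse = ", "))
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]])) {
      badSub <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(badSub) && k != "gen")
        stopLabeled("config", "unknown key(s) in ", k, ": ",
                    paste(badSub, collapse = ", "))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (!cfg$mode %in% c("tabular", "waveform"))
    stopLabeled("config", "mode must be 'tabular' or 'waveform'")
  if (is.null(cfg$models) || !length(cfg$models))
    stopLabeled("config", "config must list at least one model")
  if (cfg$cohort$nAbstinent < 1 || cfg$cohort$nNonAbstinent < 1)
    stopLabeled("config", "cohort sizes must be >= 1")
  if (cfg$mcmc$chains < 2)
    stopLabeled("config", "mcmc$chains must be >= 2")
  if (cfg$mcmc$warmup >= cfg$mcmc$iterations)
    stopLabeled("config", "mcmc warmup must be below iterations")
  genOk <- names(formals(genParams))
  badGen <- setdiff(names(cfg$gen), genOk)
  if (length(badGen))
    stopLabeled("config", "unknown generative parameter(s): ",
                paste(badGen, collapse = ", "))
  invisible(TRUE)
}

simpleHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' Executes generate -> (preprocess -> spectral -> reliability, waveform
#' mode) -> model fitting, writes TSV/JSON outputs and a run manifest, and
#' returns the in-memory results. All randomness derives from the config's
#' master seed; two runs with the same config are bit-identical on disk.
#'
#' @param config list from \code{\link{pipelineConfig}}
#' @param outDir output directory (created if needed)
#' @param quiet suppress per-stage log lines
#' @return list: manifest, table, reliability (waveform mode), fits (per
#'   model: summary, slopes, diagnostics)
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        quiet = FALSE) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, logCon)
    if (!quiet) message(msg)
  }

  params <- do.call(genParams, c(config$gen,
                                 list(seed = as.integer(config$seed))))
  layout <- buildDefaultLayout()
  logLine("stage=cohort generating ", config$cohort$nAbstinent, "+",
          config$cohort$nNonAbstinent, " participants")
  cohort <- generateCohort(config$cohort$nAbstinent,
                           config$cohort$nNonAbstinent, params)
  sp <- config$spectral
  reliability <- NULL
  retained <- NULL
  excluded <- character(0)

  if (config$mode == "tabular") {
    logLine("stage=table tabular fast path")
    table <- generateAlphaTable(cohort, layout, params)
  } else {
    graph <- nearestNeighbors(layout, config$preprocessing$neighbors)
    powerRows <- list()
    halfRows <- list()
    retained <- list()
    excluded <- character(0)
    for (i in seq_len(nrow(cohort))) {
      pid <- cohort$id[i]
      pidPower <- list()
      pidHalves <- list()
      pidRetained <- list()
      failed <- FALSE
      for (cond in c("closed", "open")) {
        logLine("stage=waveform participant=", pid, " condition=", cond)
        rec <- generateRecording(cohort[i, ], cond, layout, params,
                                 config$waveform$durationS,
                                 config$waveform$srate)
        if (params@artifactRate > 0)
          rec <- injectArtifacts(rec, params)$recording
        clean <- tryCatch(
          preprocessRecording(rec, layout, graph,
                              absThresholdUv = config$preprocessing$absThresholdUv,
                              stepThresholdUv = config$preprocessing$stepThresholdUv,
                              channelFrac = config$preprocessing$channelFrac,
                              segmentFrac = config$preprocessing$segmentFrac),
          error = function(e) {
            logLine("stage=preprocess participant=", pid, " condition=",
                    cond, " EXCLUDED: ", conditionMessage(e))
            NULL
          })
        if (is.null(clean)) { failed <- TRUE; break }
        pw <- measureAlphaPower(clean, sp$taperFraction, sp$band,
                                sp$epochAverage, sp$floorEps)
        pidPower[[cond]] <- data.frame(
          participant = pid, condition = cond, electrode = names(pw),
          log_alpha_power = as.numeric(pw), stringsAsFactors = FALSE)
        hv <- splitHalfPower(clean, sp$taperFraction, sp$band,
                             sp$epochAverage, sp$floorEps)
        pidHalves[[cond]] <- data.frame(
          participant = pid, condition = cond, electrode = names(hv$first),
          first = as.numeric(hv$first), second = as.numeric(hv$second),
          stringsAsFactors = FALSE)
        pidRetained[[paste(pid, cond, sep = "_")]] <- retainedSeconds(clean)
      }
      if (failed) {
        # an unrecoverable recording excludes the participant, not the run
        excluded <- c(excluded, pid)
      } else {
        powerRows <- c(powerRows, unname(pidPower))
        halfRows <- c(halfRows, unname(pidHalves))
        retained <- c(retained, pidRetained)
      }
    }
    if (length(excluded)) {
      logLine("stage=waveform excluded participant(s): ",
              paste(excluded, collapse = ", "))
      cohort <- cohort[!cohort$id %in% excluded, , drop = FALSE]
      if (nrow(cohort) == 0)
        stopLabeled("pipeline", "every participant was excluded")
    }
    covariates <- cohort[, c("id", "group", "sleep_quality",
                             "days_since_use")]
    table <- buildLongTable(do.call(rbind, powerRows), covariates, layout)
    logLine("stage=reliability split-half report")
    reliability <- reliabilityReport(do.call(rbind, halfRows),
                                     config$reliability$threshold)
    writeReliabilityReport(reliability,
                           file.path(outDir, "reliability.tsv"))
  }

  writeAlphaTable(table, file.path(outDir, "alpha_power.tsv"))
  utils::write.table(cohort[, c("id", "group", "sleep_quality",
                                "days_since_use")],
                     file.path(outDir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fits <- list()
  allSlopes <- list()
  for (m in config$models) {
    logLine("stage=fit model=", m)
    design <- buildDesign(table, m)
    draws <- gibbsSample(design, chains = config$mcmc$chains,
                         iterations = config$mcmc$iterations,
                         warmup = config$mcmc$warmup,
                         seed = deriveSeed(config$seed, paste0("fit", m)))
    summ <- summarizePosterior(draws)
    slopes <- NULL
    if (any(vapply(strsplit(colnames(design$X), ":", fixed = TRUE),
                   function(f) "Sleep" %in% f, logical(1)))) {
      slopes <- marginalSlopes(draws, design, model = m)
      allSlopes[[as.character(m)]] <- slopes
    }
    fit <- list(model = as.character(m),
                formula = paste(deparse(design$formula), collapse = ""),
                coefficients = summ, slopes = slopes)
    fits[[as.character(m)]] <- fit
    jsonlite::write_json(
      list(model = fit$model, formula = fit$formula,
           coefficients = summ, slopes = slopes),
      file.path(outDir, paste0("model_", m, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  if (length(allSlopes)) {
    common <- c("model", "moderator", "stratum", "group", "slope", "lower",
                "upper", "pp", "evidence", "delta")
    writeSlopeTable(do.call(rbind, lapply(allSlopes, `[`, common)),
                    file.path(outDir, "marginal_slopes.tsv"))
  }

  manifest <- list(
    config_hash = simpleHash(config),
    seed = as.integer(config$seed),
    mode = config$mode,
    software_version = tryCatch(
      as.character(utils::packageVersion("restalpha")),
      error = function(e) "dev"),
    n_participants = nrow(cohort),
    n_rows = nrow(table),
    rows_per_participant = nrow(table) / nrow(cohort),
    models = as.character(config$models),
    excluded_participants = excluded,
    retained_seconds = retained)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logLine("stage=done rows=", nrow(table))
  list(manifest = manifest, table = table, reliability = reliability,
       fits = fits, outDir = outDir)
}
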