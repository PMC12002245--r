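#' Mask all but the first minutes of each hour
#'
#' Emulates hourly subsampled monitoring where only the first
#' `keepSeconds` of every `periodSeconds` are recorded: the remainder of
#' each period is added to the recording's mask intervals, excluding it
#' from all power and ACF computation.
#'
#' @param rec a [Recording-class].
#' @param keepSeconds seconds retained at the start of each period.
#' @param periodSeconds period length.
#' @return the recording with extended mask intervals.
#' @export
maskHourlySampling <- function(rec, keepSeconds = 300,
                               periodSeconds = 3600) {
  dur <- ncol(rec@samples) / rec@rate
  starts <- seq(0, dur, by = periodSeconds)
  add <- cbind(pmin(starts + keepSeconds, dur),
               pmin(starts + periodSeconds, dur))
  add <- add[add[, 2] > add[, 1], , drop = FALSE]
  rec@maskIntervals <- rbind(rec@maskIntervals, add)
  rec
}

#' Default pipeline configuration
#'
#' @param seed global seed; every stochastic stage derives its own seed
#'   deterministically from it.
#' @param outDir output directory for all stage artifacts.
#' @param stages stages to run, in order, out of `synth`, `simulate`,
#'   `compute-tc`, `annotate`, `analyze`.
#' @param cohort named list of [cohortSpec()] arguments (seed is taken from
#'   the global seed).
#' @param sweep named list with `lambdas` and `reps` plus optional
#'   [modelConfig()] / [perturbationConfig()] arguments for the simulator
#'   stage.
#' @param alpha corrected significance level of the analysis stage.
#' @param contexts day contexts extracted by the feature stage.
#' @param hourlySampling apply [maskHourlySampling()] to each generated
#'   signal before TC windowing.
#' @return a named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(seed = 1L, outDir = "criticaltc-run",
                           stages = c("synth", "compute-tc", "annotate",
                                      "analyze"),
                           cohort = list(), sweep = list(), alpha = 0.05,
                           contexts = c("first", "last", "low_asm"),
                           hourlySampling = FALSE) {
  list(seed = seed, outDir = outDir, stages = stages, cohort = cohort,
       sweep = sweep, alpha = alpha, contexts = contexts,
       hourlySampling = hourlySampling)
}

validatePipelineConfig <- function(config) {
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("seed", "outDir", "stages"), names(config))
  if (length(miss))
    stop("missing configuration key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  allStages <- c("synth", "simulate", "compute-tc", "annotate", "analyze")
  badStage <- setdiff(config$stages, allStages)
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "),
         call. = FALSE)
  config
}

#' Run the end-to-end pipeline
#'
#' Executes the selected stages in order, writing every intermediate table
#' as CSV into the output directory plus a `manifest.json` recording the
#' configuration, derived seeds, package version and output checksums.
#' Given an identical configuration the result CSVs are byte-identical;
#' later stages read earlier stages' CSVs, so a run can be resumed from
#' any stage whose inputs already exist.
#'
#' Stage outputs: `synth` writes `subjects.csv`, `days.csv`,
#' `schedules.csv`, `scores.csv`, `epochs.csv`, `events.csv`;
#' `simulate` writes `sweep.csv` (per-run) and `sweep_summary.csv`;
#' `compute-tc` writes `features.csv`; `annotate` writes `impairment.csv`
#' and `asm_days.csv`; `analyze` writes `results.csv` and `ks.csv`.
#'
#' @param config list from [pipelineConfig()] (or a YAML file read via
#'   [readPipelineConfig()]).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  config <- validatePipelineConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  wcsv <- function(d, name) {
    write.csv(d, file.path(config$outDir, name), row.names = FALSE)
    name
  }
  written <- character()
  cohortObj <- NULL
  makeCohort <- function() {
    if (is.null(cohortObj))
      cohortObj <<- genCohort(do.call(cohortSpec,
                                      c(config$cohort,
                                        list(seed = seed + 101L))))
    cohortObj
  }
  for (stage in config$stages) {
    if (stage == "synth") {
      co <- makeCohort()
      written <- c(written, wcsv(co$subjects, "subjects.csv"),
                   wcsv(co$days, "days.csv"),
                   wcsv(co$schedules, "schedules.csv"),
                   wcsv(co$scores, "scores.csv"),
                   wcsv(co$epochs, "epochs.csv"),
                   wcsv(co$events, "events.csv"))
    } else if (stage == "simulate") {
      sw <- config$sweep
      lambdas <- if (is.null(sw$lambdas)) seq(0.8, 1.2, by = 0.05) else sw$lambdas
      reps <- if (is.null(sw$reps)) 10L else sw$reps
      cfgArgs <- sw[names(sw) %in% names(formals(modelConfig))]
      perArgs <- sw[names(sw) %in% names(formals(perturbationConfig))]
      res <- phaseSweep(lambdas, do.call(perturbationConfig, perArgs),
                        reps = reps, seed = seed + 211L,
                        config = do.call(modelConfig, cfgArgs),
                        detail = TRUE)
      written <- c(written, wcsv(attr(res, "runs"), "sweep.csv"),
                   wcsv(as.data.frame(res), "sweep_summary.csv"))
    } else if (stage == "compute-tc") {
      co <- makeCohort()
      feats <- cohortFeatures(co, contexts = config$contexts)
      written <- c(written, wcsv(feats, "features.csv"))
    } else if (stage == "annotate") {
      co <- makeCohort()
      written <- c(written, wcsv(cohortImpairment(co), "impairment.csv"))
      asm <- do.call(rbind, lapply(split(co$schedules, co$schedules$subject),
                                   function(s) {
        cl <- asmDayClasses(s)
        if (is.null(cl)) return(NULL)
        data.frame(subject = s$subject[1], high_day = cl$high,
                   low_day = cl$low)
      }))
      written <- c(written, wcsv(asm, "asm_days.csv"))
    } else if (stage == "analyze") {
      fPath <- file.path(config$outDir, "features.csv")
      iPath <- file.path(config$outDir, "impairment.csv")
      if (!file.exists(fPath) || !file.exists(iPath))
        stop("analyze stage requires features.csv and impairment.csv ",
             "in the output directory (run compute-tc and annotate first)")
      feats <- read.csv(fPath)
      imp <- read.csv(iPath)
      grid <- runComparisonGrid(feats, imp, alpha = config$alpha)
      written <- c(written, wcsv(grid$cells, "results.csv"),
                   wcsv(grid$ks, "ks.csv"))
    }
  }
  files <- file.path(config$outDir, unique(written))
  manifest <- list(
    package = "criticalTC",
    version = as.character(utils::packageVersion("criticalTC")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, stages = config$stages, config = config,
    outputs = data.frame(file = unique(written),
                         md5 = unname(tools::md5sum(files)),
                         rows = vapply(files, function(f)
                           nrow(read.csv(f)), integer(1) * 1)))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$outDir)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipelineConfig()].
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipelineConfig()
  for (k in names(cfg)) base[[k]] <- cfg[[k]]
  validatePipelineConfig(base)
}
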