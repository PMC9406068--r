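# Study orchestration: a config-driven cohort run comparing the adaptation
# strategies on synthetic phantoms, with deterministic seeding throughout.

#' Study configuration
#'
#' Describes one full comparative study: cohort size, grid, change and DIR
#' noise models, strategies, scenario set and solver settings. All
#' randomness downstream derives from `seed`.
#'
#' @param templates Anatomy templates to include.
#' @param nPhantoms Phantoms per template.
#' @param nFractions Treatment fractions simulated per phantom.
#' @param gridShape Voxel grid per axis for the cohort phantoms.
#' @param seed Master seed.
#' @param strategies Strategy tags to compare; must include `"reference"`
#'   for score differencing.
#' @param dirNoise A [dirNoiseModel()] (its seed is re-derived per fraction).
#' @param anatomyChange Named list of [anatomyChangeModel()] per template
#'   (defaults: abdominal organ motion; head-and-neck motion plus external
#'   shrinkage).
#' @param scenarios A [scenarioSet()].
#' @param solver A [solverConfig()].
#' @param outDir Optional output directory for result tables and manifest.
#' @return List of class `"StudyConfig"`.
#' @export
studyConfig <- function(templates = c("abdomen", "head_neck"),
                        nPhantoms = 3L,
                        nFractions = 3L,
                        gridShape = c(36L, 36L, 36L),
                        seed = 1L,
                        strategies = c("reference", "single_dir_1", "single_dir_2",
                                       "single_dir_3", "multi_dir", "conservative",
                                       "probabilistic", "no_adaptation"),
                        dirNoise = dirNoiseModel(),
                        anatomyChange = NULL,
                        scenarios = scenarioSet(),
                        solver = solverConfig(maxit = 200L, stages = 4L),
                        outDir = NULL) {
  stopifnot(all(templates %in% c("abdomen", "head_neck")),
            nPhantoms >= 1L, nFractions >= 1L)
  if (is.null(anatomyChange)) {
    anatomyChange <- list(
      abdomen = anatomyChangeModel(rigidShiftSdMM = 2, organDisplacementAmpMM = 6),
      head_neck = anatomyChangeModel(rigidShiftSdMM = 2, organDisplacementAmpMM = 6,
                                     externalShrinkFraction = 0.15)
    )
  }
  structure(list(
    templates = templates, nPhantoms = as.integer(nPhantoms),
    nFractions = as.integer(nFractions), gridShape = as.integer(rep_len(gridShape, 3L)),
    seed = as.integer(seed), strategies = strategies, dirNoise = dirNoise,
    anatomyChange = anatomyChange, scenarios = scenarios, solver = solver,
    outDir = outDir
  ), class = "StudyConfig")
}

# Deterministic sub-seed derivation (kept well below 2^31).
subSeed <- function(seed, ...) {
  parts <- c(...)
  s <- as.numeric(seed) %% 1000003
  for (p in parts) s <- (s * 7919 + as.numeric(p) * 104729) %% 1000003
  as.integer(s) + 1L
}

#' Run the comparative adaptation study
#'
#' For each phantom and fraction: generate the daily anatomy, simulate the
#' DIR contour ensembles, build the scenario influence matrices, build and
#' solve every requested strategy, recompute the nominal daily dose,
#' evaluate the clinical constraints, score, and difference against the
#' reference adaptation. A stage error aborts that fraction with a logged
#' reason; the study continues and failures are tabulated.
#'
#' @param config A [studyConfig()].
#' @param verbose Print progress messages.
#' @return List of class `"StudyResult"`: `results` (per phantom x fraction
#'   x strategy scores and differences), `contributions` (per-constraint
#'   contributions, input to [sensitivityAnalysis()]), `aggregate`
#'   (mean/min/max score differences per strategy and template),
#'   `failures`, and the `config`.
#' @export
runStudy <- function(config = studyConfig(), verbose = interactive()) {
  stopifnot(inherits(config, "StudyConfig"))
  if (!"reference" %in% config$strategies) {
    stop("the strategy list must include 'reference' for score differencing")
  }
  resRows <- list(); contribRows <- list(); failures <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (tpl in config$templates) {
    tps <- templatePlanSpec(tpl)
    constraints <- templateConstraints(tpl)
    beams <- templateBeams(tpl)
    for (p in seq_len(config$nPhantoms)) {
      pseed <- subSeed(config$seed, match(tpl, c("abdomen", "head_neck")), p)
      planning <- tryCatch({
        spec <- phantomSpec(tpl, gridShape = config$gridShape, seed = pseed,
                            jitterSdMM = 3, radiusJitterFrac = 0.06)
        generatePhantom(spec)
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- data.frame(
          template = tpl, phantom = p, fraction = NA_integer_,
          reason = conditionMessage(e))
        warning("phantom failed (", tpl, " p", p, "): ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(planning)) next
      spots <- placeSpots(planning, beams)
      say("[%s p%d] %d spots", tpl, p, nSpots(spots))
      planInfl <- lapply(config$scenarios, function(sc) {
        buildInfluence(planning, spots, sc)
      })
      initial <- optimizeInitialPlan(planning, constraints, planInfl, spots,
                                     nFractions = tps$nFractions,
                                     config = config$solver,
                                     extraTerms = tps$extraTerms)
      chModel <- config$anatomyChange[[tpl]]
      chModel$seed <- subSeed(pseed, 1L)
      for (f in seq_len(config$nFractions)) {
        ok <- tryCatch({
          daily <- generateFraction(planning, chModel, f)
          needsDir <- any(grepl("^single_dir_[0-9]+$", config$strategies)) ||
            any(c("multi_dir", "conservative", "probabilistic") %in% config$strategies)
          dirSets <- if (needsDir) {
            noise <- config$dirNoise
            noise$seed <- subSeed(pseed, 2L, f)
            simulateDirSets(daily, noise)
          } else list()
          dailyInfl <- lapply(config$scenarios, function(sc) {
            buildInfluence(daily, spots, sc)
          })
          nominal <- dailyInfl[[1]]
          scores <- list()
          for (strat in config$strategies) {
            built <- buildStrategyProblem(strat, daily, dirSets,
                                          clinicalSet = daily@structures,
                                          constraints = constraints,
                                          influences = dailyInfl,
                                          initialPlan = initial, spots = spots,
                                          nFractions = tps$nFractions,
                                          extraTerms = tps$extraTerms)
            plan <- if (built$type == "optimize") {
              solvePlan(built$problem, config$solver, strategy = strat)
            } else built$plan
            dose <- computeDose(nominal, planWeights(plan), tps$nFractions)
            ev <- evaluateConstraints(dose, daily@structures, constraints)
            scores[[strat]] <- scorePlan(ev)
            contribRows[[length(contribRows) + 1L]] <- data.frame(
              template = tpl, phantom = p, fraction = f, strategy = strat,
              label = ev$label, role = ev$role, value = ev$value,
              limit = ev$limit, violated = ev$violated,
              contribution = ev$contribution)
          }
          refScore <- scores[["reference"]]
          for (strat in config$strategies) {
            resRows[[length(resRows) + 1L]] <- data.frame(
              template = tpl, phantom = p, fraction = f, strategy = strat,
              score = scores[[strat]]$total,
              refScore = refScore$total,
              scoreDiff = scoreDifference(scores[[strat]], refScore),
              nViolated = scores[[strat]]$nViolated)
          }
          say("[%s p%d f%d] ref %.2f au, no-adapt diff %.2f au", tpl, p, f,
              refScore$total,
              if ("no_adaptation" %in% names(scores))
                scores[["no_adaptation"]]$total - refScore$total else NA_real_)
          TRUE
        }, error = function(e) {
          failures[[length(failures) + 1L]] <<- data.frame(
            template = tpl, phantom = p, fraction = f,
            reason = conditionMessage(e))
          warning("fraction failed (", tpl, " p", p, " f", f, "): ",
                  conditionMessage(e), call. = FALSE)
          FALSE
        })
        invisible(ok)
      }
    }
  }
  results <- do.call(rbind, resRows)
  contributions <- do.call(rbind, contribRows)
  out <- structure(list(
    results = results,
    contributions = contributions,
    aggregate = if (!is.null(results)) aggregateScores(results) else NULL,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    config = config
  ), class = "StudyResult")
  if (!is.null(config$outDir)) writeStudyResult(out, config$outDir)
  out
}

#' @export
print.StudyResult <- function(x, ...) {
  cat("Adaptation study:", nrow(x$results), "strategy evaluations\n")
  cat("Mean/min/max score difference to reference adaptation (au):\n")
  print(x$aggregate, row.names = FALSE)
  if (!is.null(x$failures)) {
    cat("Failed fractions:", nrow(x$failures), "\n")
  }
  invisible(x)
}

#' Write study result tables and manifest to a directory
#'
#' Writes `results.csv`, `contributions.csv`, `aggregate.csv` and a
#' `manifest.json` carrying the seeds, cohort layout and a hash of the
#' configuration for provenance.
#'
#' @param study A `StudyResult`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeStudyResult <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$results, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(study$contributions, file.path(dir, "contributions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$aggregate, file.path(dir, "aggregate.csv"), row.names = FALSE)
  cfg <- study$config
  manifest <- list(
    package = "adaptIMPT",
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed, templates = cfg$templates, nPhantoms = cfg$nPhantoms,
    nFractions = cfg$nFractions, gridShape = cfg$gridShape,
    strategies = cfg$strategies,
    configHash = configHash(cfg),
    failures = if (is.null(study$failures)) 0L else nrow(study$failures)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a study configuration as YAML
#'
#' Serializes every scalar/vector field plus the nested change, noise,
#' scenario and solver settings; [readStudyConfig()] restores an equivalent
#' configuration (round trip leaves the configuration unchanged).
#'
#' @param config A [studyConfig()].
#' @param file Output path (YAML).
#' @return `file`, invisibly.
#' @export
writeStudyConfig <- function(config, file) {
  stopifnot(inherits(config, "StudyConfig"))
  obj <- lapply(unclass(config), function(x) {
    if (inherits(x, c("AnatomyChangeModel", "DirNoiseModel", "SolverConfig"))) {
      unclass(x)
    } else if (is.list(x) && length(x) && inherits(x[[1]], "AnatomyChangeModel")) {
      lapply(x, unclass)
    } else x
  })
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' Read a study configuration written by [writeStudyConfig()]
#' @param file YAML path.
#' @return A [studyConfig()].
#' @export
readStudyConfig <- function(file) {
  obj <- yaml::read_yaml(file)
  noise <- do.call(dirNoiseModel, obj$dirNoise[setdiff(names(obj$dirNoise),
                                                       "maxRetries")])
  noise$maxRetries <- as.integer(obj$dirNoise$maxRetries)
  change <- lapply(obj$anatomyChange, function(m) do.call(anatomyChangeModel, m))
  solver <- do.call(solverConfig, obj$solver)
  studyConfig(
    templates = obj$templates, nPhantoms = obj$nPhantoms,
    nFractions = obj$nFractions, gridShape = obj$gridShape, seed = obj$seed,
    strategies = obj$strategies, dirNoise = noise, anatomyChange = change,
    scenarios = obj$scenarios, solver = solver, outDir = obj$outDir
  )
}

configHash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Report a study: aggregate table plus sensitivity stability
#'
#' Reproduces the mean/min/max summary per strategy and template together
#' with the scoring-weight sensitivity analysis, optionally writing both as
#' CSV.
#'
#' @param study A `StudyResult` (or a results directory written by
#'   [writeStudyResult()]).
#' @param multipliers Scoring-weight multipliers for the sensitivity scan.
#' @param outDir Optional directory for `report_aggregate.csv` and
#'   `report_sensitivity.csv`.
#' @return List with `aggregate`, `sensitivity`.
#' @export
reportStudy <- function(study, multipliers = 1:10, outDir = NULL) {
  if (is.character(study)) {
    results <- utils::read.csv(file.path(study, "results.csv"))
    contributions <- utils::read.csv(file.path(study, "contributions.csv"))
    study <- list(results = results, contributions = contributions,
                  aggregate = aggregateScores(results))
  }
  sens <- sensitivityAnalysis(study$contributions, multipliers)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(study$aggregate, file.path(outDir, "report_aggregate.csv"),
                     row.names = FALSE)
    utils::write.csv(sens$table, file.path(outDir, "report_sensitivity.csv"),
                     row.names = FALSE)
  }
  list(aggregate = study$aggregate, sensitivity = sens)
}
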