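# The adaptation strategies: how the daily structure information (clinical
# contours, DIR-propagated contour ensembles, or combinations of them) is
# turned into a robust optimization problem — or, for no adaptation, into a
# dose recomputation of the initial plan.

STRATEGY_TAGS <- c("multi_dir", "conservative", "probabilistic", "reference",
                   "no_adaptation")

# Objective weight given to hard vs soft constraints during optimization
# (importance affects optimization, not scoring).
defaultImportanceWeights <- function() c(hard = 10, soft = 1)

# Per-template course prescription and planning extras. The extra terms are
# mild target dose caps applied identically across all strategies; the
# evaluation/scoring constraint list is templateConstraints() alone.
templatePlanSpec <- function(template) {
  if (template == "abdomen") {
    list(nFractions = 5, prescriptionGy = 50,
         extraTerms = list(list(structure = "ctv", kind = "max_dose",
                                doseGy = 60, volume = NA_real_, weight = 1)))
  } else if (template == "head_neck") {
    list(nFractions = 30, prescriptionGy = 70,
         extraTerms = list(list(structure = "ctv_high", kind = "max_dose",
                                doseGy = 76, volume = NA_real_, weight = 1)))
  } else stop("unknown template '", template, "'")
}

# Map one constraint row to an objective term spec (kind/level/volume).
constraintToTermSpec <- function(row, structVolCC) {
  if (row$metric == "v_pct" && row$direction == "lower") {
    # coverage: smooth min-dose surrogate at the constraint's dose level
    list(kind = "min_dose", doseGy = row$doseGy, volume = NA_real_)
  } else if (row$metric == "v_pct" && row$direction == "upper") {
    list(kind = "dvh_upper", doseGy = row$doseGy,
         volume = row$limit / 100 * structVolCC)
  } else if (row$metric == "v_cc" && row$direction == "upper") {
    list(kind = "dvh_upper", doseGy = row$doseGy, volume = row$limit)
  } else if (row$metric == "v_cc" && row$direction == "lower") {
    list(kind = "dvh_lower", doseGy = row$doseGy,
         volume = 100 * row$limit / structVolCC)
  } else if (row$metric == "mean" && row$direction == "upper") {
    list(kind = "mean_upper", doseGy = row$limit, volume = NA_real_)
  } else if (row$metric == "max" && row$direction == "upper") {
    list(kind = "max_dose", doseGy = row$limit, volume = NA_real_)
  } else if (row$metric == "sparing" && row$direction == "lower") {
    # keep V(d) below (total volume - required spared volume)
    list(kind = "dvh_upper", doseGy = row$doseGy,
         volume = max(0, structVolCC - row$limit))
  } else {
    stop("no objective mapping for metric '", row$metric, "' direction '",
         row$direction, "'")
  }
}

# Evaluation/optimization mask for one constraint row on a structure set,
# honouring the `exclude` column (with its dilation margin).
constraintMask <- function(row, structSet) {
  m <- getMask(structSet, row$structure)
  if (nzchar(row$exclude) && !is.na(row$exclude)) {
    ex <- getMask(structSet, row$exclude)
    if (row$excludeMarginMM > 0) {
      ex <- dilateMask(ex, voxelSpacing(structSet), row$excludeMarginMM)
    }
    m <- m & !ex
  }
  m
}

constraintMaskIdx <- function(row, structSet) {
  idx <- which(constraintMask(row, structSet))
  if (length(idx)) idx else NULL
}

# Build the composite objective (list of resolved terms) for one structure
# set from the constraint table. Empty masks are skipped (with the
# conservative empty-intersection case in mind).
objectivesFromConstraints <- function(constraints, structSet, spacing,
                                      importanceWeights = defaultImportanceWeights(),
                                      extraTerms = NULL) {
  voxcc <- voxelVolumeCC(spacing)
  terms <- list()
  for (i in seq_len(nrow(constraints))) {
    row <- constraints[i, ]
    idx <- constraintMaskIdx(row, structSet)
    if (is.null(idx)) next
    spec <- constraintToTermSpec(row, structVolCC = length(idx) * voxcc)
    tm <- objectiveTerm(row$structure, spec$kind, spec$doseGy, spec$volume,
                        weight = unname(importanceWeights[[row$importance]]))
    terms[[length(terms) + 1L]] <- resolveTerm(tm, idx)
  }
  for (et in extraTerms %||% list()) {
    if (!et$structure %in% structureNames(structSet)) next
    m <- getMask(structSet, et$structure)
    idx <- which(m)
    if (!length(idx)) next
    tm <- objectiveTerm(et$structure, et$kind, et$doseGy, et$volume, et$weight)
    terms[[length(terms) + 1L]] <- resolveTerm(tm, idx)
  }
  if (!length(terms)) stop("no non-empty objective terms could be built")
  terms
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Probabilistic composite: each constraint-derived term is replicated per
# agreement level with weight scaled by the exact voxel-classification
# frequency k/K.
probabilisticObjectives <- function(constraints, dirSets, spacing,
                                    importanceWeights = defaultImportanceWeights(),
                                    extraTerms = NULL) {
  K <- length(dirSets)
  am <- agreementMap(dirSets)
  subs <- substructurePartition(am, K)
  voxcc <- voxelVolumeCC(spacing)
  levelIdx <- function(structure, k, excl, exclMarginMM = 0) {
    lvl <- subs@levels[[structure]][[as.character(round(100 * k / K))]]
    if (nzchar(excl) && !is.na(excl)) {
      exclMask <- maskUnion(lapply(dirSets, getMask, name = excl))
      if (exclMarginMM > 0) exclMask <- dilateMask(exclMask, spacing, exclMarginMM)
      lvl <- lvl & !exclMask
    }
    which(lvl)
  }
  terms <- list()
  addLevels <- function(structure, kind, doseGy, volumeFor, baseWeight, excl = "",
                        exclMarginMM = 0) {
    for (k in seq_len(K)) {
      idx <- levelIdx(structure, k, excl, exclMarginMM)
      if (!length(idx)) next
      tm <- objectiveTerm(structure, kind, doseGy, volumeFor(length(idx) * voxcc),
                          weight = baseWeight * k / K)
      terms[[length(terms) + 1L]] <<- resolveTerm(tm, idx)
    }
  }
  for (i in seq_len(nrow(constraints))) {
    row <- constraints[i, ]
    if (!row$structure %in% names(subs@levels)) next
    unionVolCC <- sum(vapply(seq_len(K), function(k) {
      length(levelIdx(row$structure, k, row$exclude, row$excludeMarginMM))
    }, numeric(1))) * voxcc
    spec <- constraintToTermSpec(row, structVolCC = max(unionVolCC, voxcc))
    addLevels(row$structure, spec$kind, spec$doseGy, function(cc) spec$volume,
              baseWeight = unname(importanceWeights[[row$importance]]),
              excl = row$exclude, exclMarginMM = row$excludeMarginMM)
  }
  for (et in extraTerms %||% list()) {
    if (!et$structure %in% names(subs@levels)) next
    addLevels(et$structure, et$kind, et$doseGy, function(cc) et$volume,
              baseWeight = et$weight)
  }
  if (!length(terms)) stop("no non-empty probabilistic objective terms could be built")
  terms
}

#' Build the optimization problem (or fixed plan) for one adaptation strategy
#'
#' Strategy roster:
#' * `single_dir_k`: the k-th DIR-propagated structure set, used directly
#'   without correction; pairs = that objective x all scenarios.
#' * `multi_dir`: worst-case optimization over all K propagated structure
#'   sets in parallel; pairs = K objectives x all scenarios.
#' * `conservative`: [conservativeCombination()] of the ensemble (target
#'   intersection under a stereotactic prescription, union under coverage;
#'   organ unions), then as single-DIR.
#' * `probabilistic`: exact-level agreement substructures; each constraint
#'   term is replicated per level with weight scaled by k/K.
#' * `reference`: the clinical (physician-ground-truth) structures.
#' * `no_adaptation`: no optimization; the initial plan's weights are
#'   returned unchanged for dose recomputation on the daily anatomy.
#'
#' All strategies are built from the same constraint list; only the
#' structure sets and weights differ.
#'
#' @param strategy Strategy tag (see above).
#' @param daily The daily [Phantom-class].
#' @param dirSets List of simulated DIR structure sets ([simulateDirSets()]).
#' @param clinicalSet The clinical [StructureSet-class] of the fraction.
#' @param constraints The template [constraintTable()].
#' @param influences List of scenario [InfluenceMatrix-class] objects on the
#'   daily anatomy.
#' @param initialPlan The initial [Plan-class] (needed for `no_adaptation`).
#' @param spots The shared [SpotGrid-class].
#' @param nFractions Fractions per course.
#' @param importanceWeights Named weights for hard/soft constraints.
#' @param extraTerms Template-level extra objective terms (target dose caps),
#'   identical across strategies.
#' @return `list(type = "optimize", problem = <RobustProblem>)` or
#'   `list(type = "fixed", plan = <Plan>)`.
#' @export
buildStrategyProblem <- function(strategy, daily, dirSets, clinicalSet,
                                 constraints, influences, initialPlan = NULL,
                                 spots, nFractions = 1,
                                 importanceWeights = defaultImportanceWeights(),
                                 extraTerms = NULL) {
  spacing <- voxelSpacing(daily)
  singleLike <- function(structSet) {
    obj <- objectivesFromConstraints(constraints, structSet, spacing,
                                     importanceWeights, extraTerms)
    robustProblem(list(obj), influences, spots = spots,
                  nFractions = nFractions, spacing = spacing)
  }
  if (grepl("^single_dir_[0-9]+$", strategy)) {
    k <- as.integer(sub("^single_dir_", "", strategy))
    if (k < 1L || k > length(dirSets)) {
      stop("strategy '", strategy, "' refers to a missing DIR set")
    }
    return(list(type = "optimize", problem = singleLike(dirSets[[k]])))
  }
  switch(strategy,
    multi_dir = {
      objs <- lapply(dirSets, function(s) {
        objectivesFromConstraints(constraints, s, spacing, importanceWeights,
                                  extraTerms)
      })
      # structurally identical structure sets give identical objectives;
      # deduplicate so K identical sets reduce exactly to the single-DIR problem
      objs <- objs[!duplicated(objs)]
      list(type = "optimize",
           problem = robustProblem(objs, influences, spots = spots,
                                   nFractions = nFractions, spacing = spacing))
    },
    conservative = {
      comb <- conservativeCombination(dirSets)
      list(type = "optimize", problem = singleLike(comb))
    },
    probabilistic = {
      obj <- probabilisticObjectives(constraints, dirSets, spacing,
                                     importanceWeights, extraTerms)
      list(type = "optimize",
           problem = robustProblem(list(obj), influences, spots = spots,
                                   nFractions = nFractions, spacing = spacing))
    },
    reference = list(type = "optimize", problem = singleLike(clinicalSet)),
    no_adaptation = {
      if (is.null(initialPlan)) stop("no_adaptation requires the initial plan")
      plan <- initialPlan
      plan@strategy <- "no_adaptation"
      list(type = "fixed", plan = plan)
    },
    stop("unknown strategy tag '", strategy, "'")
  )
}

#' Optimize the initial (planning-anatomy) plan
#'
#' Solves the reference problem on the planning anatomy: clinical planning
#' structures, the template constraint list, robust over the scenario set.
#' This plan seeds `no_adaptation` and fixes the beam/spot geometry and
#' constraint weights reused by every adaptive strategy.
#'
#' @param planning The planning [Phantom-class].
#' @param constraints The template [constraintTable()].
#' @param influences Scenario influences on the planning anatomy.
#' @param spots The [SpotGrid-class].
#' @param nFractions Fractions per course.
#' @param config A [solverConfig()].
#' @param importanceWeights,extraTerms As in [buildStrategyProblem()].
#' @return A [Plan-class] tagged `"initial"`.
#' @export
optimizeInitialPlan <- function(planning, constraints, influences, spots,
                                nFractions = 1, config = solverConfig(),
                                importanceWeights = defaultImportanceWeights(),
                                extraTerms = NULL) {
  obj <- objectivesFromConstraints(constraints, planning@structures,
                                   voxelSpacing(planning), importanceWeights,
                                   extraTerms)
  prob <- robustProblem(list(obj), influences, spots = spots,
                        nFractions = nFractions, spacing = voxelSpacing(planning))
  solvePlan(prob, config, strategy = "initial")
}
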