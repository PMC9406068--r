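# Plan-quality scoring: constraint evaluation on clinical structures, the
# violation-sum score in arbitrary units (au), reference differencing,
# cohort aggregation, and the scoring-weight sensitivity analysis.

#' Evaluate a constraint list on a dose distribution
#'
#' Every constraint is evaluated with [doseMetric()] on the *clinical*
#' structures, regardless of which structures the plan was optimized on.
#' A constraint is violated when the value exceeds an upper limit or falls
#' short of a lower limit; a value exactly at the limit is not a violation.
#' The per-constraint contribution is `|C - Cref| * scoreWeight` when
#' violated and 0 otherwise, in the metric's native unit (percentage
#' points, cc, or Gy).
#'
#' @param dose Numeric 3D dose grid (Gy-RBE per course).
#' @param structures The clinical [StructureSet-class].
#' @param constraints A [constraintTable()].
#' @return data.frame: one row per constraint with `value`, `violated`,
#'   `contribution` and a `role` column from the structure set.
#' @export
evaluateConstraints <- function(dose, structures, constraints) {
  stopifnot(is(structures, "StructureSet"), inherits(constraints, "data.frame"))
  roles <- structureRoles(structures)
  spacing <- voxelSpacing(structures)
  out <- constraints
  out$value <- NA_real_
  out$violated <- FALSE
  out$contribution <- 0
  out$role <- NA_character_
  for (i in seq_len(nrow(constraints))) {
    row <- constraints[i, ]
    if (!row$structure %in% names(roles)) {
      stop("constraint references missing structure '", row$structure, "'")
    }
    m <- constraintMask(row, structures)
    if (!any(m)) {
      stop("constraint on '", row$structure, "' evaluates on an empty mask")
    }
    C <- doseMetric(dose, m, row$metric, row$doseGy, spacing)
    viol <- (row$direction == "upper" && C > row$limit) ||
      (row$direction == "lower" && C < row$limit)
    out$value[i] <- C
    out$violated[i] <- viol
    out$contribution[i] <- if (viol) abs(C - row$limit) * row$scoreWeight else 0
    out$role[i] <- roles[[row$structure]]
  }
  out
}

#' Plan-quality score
#'
#' Sums the violation contributions of an evaluated constraint list into a
#' single score in arbitrary units (au): each violated constraint adds the
#' absolute distance of its value to the limit (times its scoring weight),
#' native units mixed. The score is 0 exactly when all constraints are
#' met; lower is better. For example, a brainstem maximum of 55 Gy against
#' a 54 Gy limit contributes 1 au; a target hot-spot volume of 1.1 cc
#' against a 1 cc limit contributes 0.1 au.
#'
#' @param evaluated Output of [evaluateConstraints()].
#' @return List of class `"ScoreReport"`: `total` (au), `nViolated`,
#'   `constraints` (the evaluated table).
#' @export
scorePlan <- function(evaluated) {
  stopifnot(all(c("contribution", "violated") %in% names(evaluated)))
  structure(list(
    total = sum(evaluated$contribution),
    nViolated = sum(evaluated$violated),
    constraints = evaluated
  ), class = "ScoreReport")
}

#' @export
print.ScoreReport <- function(x, ...) {
  cat("Plan-quality score:", signif(x$total, 6), "au (", x$nViolated,
      "violated constraints )\n")
  v <- x$constraints[x$constraints$violated, c("label", "value", "limit", "contribution")]
  if (nrow(v)) print(v, row.names = FALSE)
  invisible(x)
}

#' Score difference to the reference plan
#'
#' Signed difference `score - reference score`, computed per phantom and
#' fraction to remove the anatomy-dependent baseline. Both scores must come
#' from the same constraint list.
#'
#' @param score,reference [scorePlan()] reports for the same
#'   phantom/fraction.
#' @return Signed difference in au.
#' @export
scoreDifference <- function(score, reference) {
  stopifnot(inherits(score, "ScoreReport"), inherits(reference, "ScoreReport"))
  if (!identical(score$constraints$label, reference$constraints$label)) {
    stop("score and reference were computed from different constraint lists")
  }
  score$total - reference$total
}

#' Aggregate study scores per strategy and template
#'
#' Mean, minimum and maximum of the score differences to the reference
#' adaptation, per strategy and template (the reporting shape of the
#' comparative study).
#'
#' @param results data.frame with columns `template`, `strategy`,
#'   `scoreDiff` (one row per phantom x fraction x strategy).
#' @return data.frame with `template`, `strategy`, `mean`, `min`, `max`, `n`.
#' @export
aggregateScores <- function(results) {
  stopifnot(all(c("template", "strategy", "scoreDiff") %in% names(results)))
  sp <- split(results, list(results$template, results$strategy), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(template = g$template[1], strategy = g$strategy[1],
               mean = mean(g$scoreDiff), min = min(g$scoreDiff),
               max = max(g$scoreDiff), n = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$template, out$mean), ]
}

#' Scoring-weight sensitivity analysis
#'
#' Recomputes the study score totals with the target constraints (or the
#' organ constraints) weighted by multipliers relative to the other
#' structures, and reports the strategy rankings (by mean score difference
#' to reference, per template) under each setting. Multiplying all weights
#' by a common factor leaves rankings unchanged, so only the relative
#' multiplier matters; multiplier 1 reproduces the original ranking.
#'
#' @param contributions Per-constraint contribution table from [runStudy()]
#'   (columns `template`, `phantom`, `fraction`, `strategy`, `role`,
#'   `contribution`).
#' @param multipliers Integer multipliers to scan (default 1:10).
#' @return List with `table` (template, mode, multiplier, strategy, mean
#'   score difference, rank) and `stability` (per template and mode: do the
#'   best and worst strategies keep their identity across all multipliers).
#' @export
sensitivityAnalysis <- function(contributions, multipliers = 1:10) {
  need <- c("template", "phantom", "fraction", "strategy", "role", "contribution")
  stopifnot(all(need %in% names(contributions)))
  if (!"reference" %in% contributions$strategy) {
    stop("sensitivity analysis requires the reference strategy")
  }
  rows <- list()
  for (mode in c("target", "organ")) {
    boosted <- if (mode == "target") "target" else "oar"
    for (m in multipliers) {
      dat <- contributions
      dat$weighted <- dat$contribution * ifelse(dat$role == boosted, m, 1)
      tot <- stats::aggregate(weighted ~ template + phantom + fraction + strategy,
                              data = dat, FUN = sum)
      names(tot)[5] <- "total"
      ref <- tot[tot$strategy == "reference",
                 c("template", "phantom", "fraction", "total")]
      names(ref)[4] <- "refTotal"
      tot <- merge(tot, ref, by = c("template", "phantom", "fraction"))
      tot$diff <- tot$total - tot$refTotal
      agg <- stats::aggregate(diff ~ template + strategy, data = tot, FUN = mean)
      for (tpl in unique(agg$template)) {
        g <- agg[agg$template == tpl, ]
        g <- g[order(g$diff), ]
        g$rank <- seq_len(nrow(g))
        rows[[length(rows) + 1L]] <- data.frame(
          template = tpl, mode = mode, multiplier = m,
          strategy = g$strategy, meanDiff = g$diff, rank = g$rank)
      }
    }
  }
  tab <- do.call(rbind, rows)
  stab <- do.call(rbind, lapply(split(tab, list(tab$template, tab$mode), drop = TRUE),
    function(g) {
      best <- vapply(split(g, g$multiplier),
                     function(h) h$strategy[which.min(h$meanDiff)], character(1))
      worst <- vapply(split(g, g$multiplier),
                      function(h) h$strategy[which.max(h$meanDiff)], character(1))
      data.frame(template = g$template[1], mode = g$mode[1],
                 best = best[1], bestStable = length(unique(best)) == 1L,
                 worst = worst[1], worstStable = length(unique(worst)) == 1L)
    }))
  rownames(stab) <- NULL
  list(table = tab, stability = stab)
}
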