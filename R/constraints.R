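# Clinical constraint specifications in the planning-table dialect, e.g.
# "V33Gy < 1 cc", "V47.5Gy > 95%", "mean < 10Gy", "max < 54Gy",
# "Vtot-V15Gy > 700 cc". Constraints parse from and serialize to this
# dialect; each row carries an importance (hard/soft) and a scoring weight.

#' Parse a constraint expression
#'
#' @param text Constraint in the table dialect (see examples).
#' @return List with `metric` (`v_pct`/`v_cc`/`mean`/`max`/`sparing`),
#'   `doseGy`, `limit`, `unit` and `direction` (`upper`/`lower`).
#' @examples
#' parseConstraintText("V47.5Gy > 95%")
#' parseConstraintText("Vtot-V15Gy > 700 cc")
#' @export
parseConstraintText <- function(text) {
  s <- gsub("\\s+", "", text)
  num <- "([0-9]+\\.?[0-9]*)"
  m <- regmatches(s, regexec(paste0("^V_?tot_?-V", num, "(Gy)?([<>])", num, "cc$"), s))[[1]]
  if (length(m)) {
    dir <- if (m[4] == ">") "lower" else "upper"
    return(list(metric = "sparing", doseGy = as.numeric(m[2]),
                limit = as.numeric(m[5]), unit = "cc", direction = dir))
  }
  m <- regmatches(s, regexec(paste0("^V", num, "(Gy)?([<>])", num, "(%|cc)$"), s))[[1]]
  if (length(m)) {
    dir <- if (m[4] == ">") "lower" else "upper"
    metric <- if (m[6] == "%") "v_pct" else "v_cc"
    return(list(metric = metric, doseGy = as.numeric(m[2]),
                limit = as.numeric(m[5]), unit = m[6], direction = dir))
  }
  m <- regmatches(s, regexec(paste0("^(mean|max)([<>])", num, "(Gy)?(-RBE)?$"), s))[[1]]
  if (length(m)) {
    dir <- if (m[3] == ">") "lower" else "upper"
    return(list(metric = m[2], doseGy = NA_real_,
                limit = as.numeric(m[4]), unit = "Gy", direction = dir))
  }
  stop("cannot parse constraint expression '", text, "'")
}

#' Format a parsed constraint back into the table dialect
#' @param row One row of a constraint table (as a list or 1-row data.frame).
#' @return Character scalar.
#' @export
formatConstraintText <- function(row) {
  op <- if (row$direction == "lower") ">" else "<"
  switch(row$metric,
    v_pct = sprintf("V%gGy %s %g%%", row$doseGy, op, row$limit),
    v_cc = sprintf("V%gGy %s %g cc", row$doseGy, op, row$limit),
    mean = sprintf("mean %s %gGy", op, row$limit),
    max = sprintf("max %s %gGy", op, row$limit),
    sparing = sprintf("Vtot-V%gGy %s %g cc", row$doseGy, op, row$limit)
  )
}

#' Build a constraint table
#'
#' @param structure Structure names.
#' @param text Constraint expressions in the table dialect.
#' @param importance `"hard"` or `"soft"` per row.
#' @param scoreWeight Scoring weight per row (default 1: all constraints
#'   weighted equally in the plan-quality score).
#' @param exclude Optional structure name to exclude from the evaluation
#'   mask (e.g. a boost volume nested inside the structure), `""` for none.
#' @param excludeMarginMM Margin (mm) by which the excluded structure is
#'   expanded before subtraction, as used clinically to carve the planned
#'   dose gradient around a boost volume out of an intermediate-dose
#'   evaluation structure.
#' @return data.frame of class `"ConstraintTable"` with one parsed row per
#'   constraint.
#' @export
constraintTable <- function(structure, text, importance, scoreWeight = 1,
                            exclude = "", excludeMarginMM = 0) {
  stopifnot(length(structure) == length(text), length(text) == length(importance))
  if (!all(importance %in% c("hard", "soft"))) {
    stop("importance must be 'hard' or 'soft'")
  }
  scoreWeight <- rep_len(scoreWeight, length(text))
  exclude <- rep_len(exclude, length(text))
  excludeMarginMM <- rep_len(excludeMarginMM, length(text))
  if (any(scoreWeight < 0)) stop("scoreWeight must be >= 0")
  parsed <- lapply(text, parseConstraintText)
  out <- data.frame(
    structure = structure,
    label = paste(structure, vapply(text, function(x) gsub("\\s+", "", x), character(1))),
    text = text,
    metric = vapply(parsed, `[[`, character(1), "metric"),
    doseGy = vapply(parsed, `[[`, numeric(1), "doseGy"),
    limit = vapply(parsed, `[[`, numeric(1), "limit"),
    unit = vapply(parsed, `[[`, character(1), "unit"),
    direction = vapply(parsed, `[[`, character(1), "direction"),
    importance = importance,
    scoreWeight = scoreWeight,
    exclude = exclude,
    excludeMarginMM = ifelse(is.na(excludeMarginMM), 0, excludeMarginMM),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ConstraintTable", "data.frame")
  out
}

#' Read a constraint table from CSV
#'
#' Expected columns: `structure`, `constraint`, `importance`; optional
#' `scoreWeight` and `exclude`.
#'
#' @param file Path to a CSV file in the constraint dialect.
#' @return A [constraintTable()].
#' @export
readConstraints <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("structure", "constraint", "importance")
  if (!all(need %in% names(df))) {
    stop("constraint CSV must have columns: ", paste(need, collapse = ", "))
  }
  constraintTable(df$structure, df$constraint, df$importance,
                  scoreWeight = if ("scoreWeight" %in% names(df)) df$scoreWeight else 1,
                  exclude = if ("exclude" %in% names(df)) df$exclude else "",
                  excludeMarginMM = if ("excludeMarginMM" %in% names(df))
                    df$excludeMarginMM else 0)
}

#' Write a constraint table to CSV (round-trips through [readConstraints()])
#' @param constraints A [constraintTable()].
#' @param file Output path.
#' @export
writeConstraints <- function(constraints, file) {
  out <- data.frame(
    structure = constraints$structure,
    constraint = vapply(seq_len(nrow(constraints)), function(i) {
      formatConstraintText(constraints[i, ])
    }, character(1)),
    importance = constraints$importance,
    scoreWeight = constraints$scoreWeight,
    exclude = constraints$exclude,
    excludeMarginMM = constraints$excludeMarginMM
  )
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Clinical constraint set of a template
#'
#' The planning/evaluation constraint list shipped with each anatomy
#' template (read from the package's `extdata`). The abdominal list follows
#' a stereotactic prescription of 50 Gy-RBE in 5 fractions; the head and
#' neck list a standard fractionation of 70/54 Gy-RBE in 30 fractions. For
#' the nested head-and-neck CTVs, the low-risk hot-spot row is evaluated on
#' the low-risk volume excluding the boost volume.
#'
#' @param template `"abdomen"` or `"head_neck"`.
#' @return A [constraintTable()].
#' @export
templateConstraints <- function(template) {
  file <- system.file("extdata",
                      paste0(template, "_constraints.csv"),
                      package = "adaptIMPT", mustWork = FALSE)
  if (!nzchar(file)) {
    stop("no constraint table shipped for template '", template, "'")
  }
  readConstraints(file)
}
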