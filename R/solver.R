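# Worst-case (minimax) spot-weight optimization: minimize the maximum
# composite objective over (structure-set alternative x error scenario)
# pairs, subject to nonnegative weights. The nonsmooth maximum is smoothed
# with a log-sum-exp of temperature tau, annealed over a few stages, each
# minimized with bound-constrained L-BFGS; a stage result is accepted only
# if the true (unsmoothed) maximum decreased, so the recorded objective
# history is monotone.

#' Robust optimization problem
#'
#' The cross-product of structure-set objective alternatives and error
#' scenarios: each pair couples one composite objective (a list of resolved
#' terms) with one influence matrix. All pairs share the spot roster.
#'
#' @param objectives List of composite objectives (lists of terms with
#'   resolved voxel indices).
#' @param influences List of [InfluenceMatrix-class] objects (one per
#'   scenario), shared across objectives.
#' @param pairs data.frame with columns `obj` and `infl` indexing the two
#'   lists; defaults to the full cross-product.
#' @param spots The [SpotGrid-class] the influences were built for.
#' @param nFractions Fractions per course (dose is optimized per course).
#' @param spacing Voxel spacing in mm.
#' @return List of class `"RobustProblem"`.
#' @export
robustProblem <- function(objectives, influences, pairs = NULL, spots,
                          nFractions = 1, spacing) {
  stopifnot(length(objectives) >= 1L, length(influences) >= 1L)
  nsp <- vapply(influences, function(im) nrow(im@dose), integer(1))
  if (length(unique(nsp)) != 1L) stop("all influence matrices must share the spot roster")
  if (is.null(pairs)) {
    pairs <- expand.grid(obj = seq_along(objectives), infl = seq_along(influences))
  }
  stopifnot(nrow(pairs) >= 1L)
  structure(list(objectives = objectives, influences = influences,
                 pairs = pairs, spots = spots, nFractions = nFractions,
                 spacing = spacing),
            class = "RobustProblem")
}

#' Solver configuration
#'
#' @param maxit Total quasi-Newton iteration budget (split over the
#'   annealing stages).
#' @param stages Number of log-sum-exp annealing stages.
#' @param tauInit Initial smoothing temperature; default 20% of the initial
#'   worst-pair objective.
#' @param tauFactor Multiplicative temperature decrease per stage.
#' @param tolF Relative objective-decrease tolerance used in the
#'   convergence report.
#' @param w0 Optional initial weights; default is a uniform positive vector
#'   scaled so the mean target dose of the first pair matches its highest
#'   coverage level.
#' @return List of class `"SolverConfig"`.
#' @export
solverConfig <- function(maxit = 150L, stages = 3L, tauInit = NULL,
                         tauFactor = 0.2, tolF = 1e-6, w0 = NULL) {
  stopifnot(maxit >= 1L, stages >= 1L, tauFactor > 0, tauFactor < 1)
  structure(list(maxit = as.integer(maxit), stages = as.integer(stages),
                 tauInit = tauInit, tauFactor = tauFactor, tolF = tolF, w0 = w0),
            class = "SolverConfig")
}

# Uniform positive initial weights scaled to the first objective's highest
# coverage level (min_dose, else dvh_lower) on the first influence.
autoInitWeights <- function(problem) {
  nsp <- nrow(problem$influences[[1]]@dose)
  terms <- problem$objectives[[1]]
  lvl <- NA_real_; idx <- NULL
  for (tm in terms) {
    if (tm$kind %in% c("min_dose", "dvh_lower") &&
        (is.na(lvl) || tm$doseGy > lvl)) {
      lvl <- tm$doseGy; idx <- tm$maskIdx
    }
  }
  w <- rep(1, nsp)
  if (!is.na(lvl) && length(idx)) {
    d1 <- as.numeric(Matrix::crossprod(problem$influences[[1]]@dose, w)) *
      problem$nFractions
    md <- mean(d1[idx])
    if (is.finite(md) && md > 0) w <- rep(lvl / md, nsp)
  }
  w
}

#' Solve a robust spot-weight optimization problem
#'
#' Minimizes the maximum composite objective over all pairs subject to
#' `weights >= 0` (annealed smoothed-maximum quasi-Newton; see above).
#' Deterministic given the problem and configuration; the recorded
#' objective history never increases across accepted stages. A single pair
#' reduces to plain composite minimization. If the iteration budget is
#' exhausted while the objective is still improving, the best iterate is
#' returned with `converged = FALSE`.
#'
#' @param problem A [robustProblem()].
#' @param config A [solverConfig()].
#' @param strategy Strategy tag recorded on the returned plan.
#' @return A [Plan-class] with solver diagnostics (`iterations`,
#'   `objective`, `converged`, `history`, `pairValues`).
#' @export
solvePlan <- function(problem, config = solverConfig(), strategy = "plan") {
  stopifnot(inherits(problem, "RobustProblem"))
  nFx <- problem$nFractions
  voxcc <- voxelVolumeCC(problem$spacing)
  pairs <- problem$pairs

  # Restrict the dose computation to voxels any objective term touches.
  voxUsed <- sort(unique(unlist(lapply(problem$objectives, function(terms) {
    unlist(lapply(terms, `[[`, "maskIdx"))
  }))))
  nvoxFull <- ncol(problem$influences[[1]]@dose)
  remap <- integer(nvoxFull)
  remap[voxUsed] <- seq_along(voxUsed)
  objR <- lapply(problem$objectives, function(terms) {
    lapply(terms, function(tm) { tm$maskIdx <- remap[tm$maskIdx]; tm })
  })
  inflUsed <- sort(unique(pairs$infl))
  A <- vector("list", length(problem$influences))
  for (i in inflUsed) A[[i]] <- problem$influences[[i]]@dose[, voxUsed, drop = FALSE]
  nsp <- nrow(problem$influences[[1]]@dose)

  pairEvals <- function(w, gradient = FALSE) {
    doses <- vector("list", length(A))
    for (i in inflUsed) {
      doses[[i]] <- as.numeric(Matrix::crossprod(A[[i]], w)) * nFx
    }
    lapply(seq_len(nrow(pairs)), function(p) {
      compositeEval(objR[[pairs$obj[p]]], doses[[pairs$infl[p]]], voxcc,
                    gradient = gradient)
    })
  }
  trueMax <- function(w) {
    max(vapply(pairEvals(w), `[[`, numeric(1), "value"))
  }

  w <- if (!is.null(config$w0)) as.numeric(config$w0) else autoInitWeights(problem)
  if (length(w) != nsp) stop("initial weights must match the spot count")
  if (any(w < 0)) stop("initial weights must be >= 0")

  fTrue <- trueMax(w)
  history <- fTrue
  tau0 <- config$tauInit
  if (is.null(tau0)) tau0 <- max(0.2 * fTrue, 1e-8)
  taus <- tau0 * config$tauFactor^(seq_len(config$stages) - 1)
  stageIter <- max(5L, ceiling(config$maxit / config$stages))
  totalIter <- 0L
  lastConv <- 0L
  fBeforeLast <- fTrue

  # cache: optim calls fn and gr at the same point back to back
  cache <- new.env(parent = emptyenv())
  evalAt <- function(w, tau) {
    key <- c(tau, w)
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    evs <- pairEvals(w, gradient = TRUE)
    f <- vapply(evs, `[[`, numeric(1), "value")
    M <- max(f)
    e <- exp((f - M) / tau)
    p <- e / sum(e)
    val <- M + tau * log(sum(e))
    g <- numeric(length(w))
    for (pp in seq_len(nrow(pairs))) {
      if (p[pp] > 1e-12) {
        g <- g + p[pp] * as.numeric(A[[pairs$infl[pp]]] %*% evs[[pp]]$grad) * nFx
      }
    }
    cache$key <- key
    cache$val <- list(value = val, grad = g)
    cache$val
  }

  for (tau in taus) {
    if (fTrue <= 1e-14) break
    res <- stats::optim(
      w,
      fn = function(ww) evalAt(ww, tau)$value,
      gr = function(ww) evalAt(ww, tau)$grad,
      method = "L-BFGS-B", lower = 0,
      control = list(maxit = stageIter, factr = 1e7)
    )
    totalIter <- totalIter + unname(res$counts["function"])
    lastConv <- res$convergence
    res$par <- pmax(0, res$par)  # guard against bound round-off
    fNew <- trueMax(res$par)
    fBeforeLast <- fTrue
    if (fNew <= fTrue) {
      w <- res$par
      fTrue <- fNew
      history <- c(history, fNew)
    }
  }

  stillImproving <- (fBeforeLast - fTrue) > config$tolF * (1 + abs(fTrue))
  converged <- !(lastConv == 1L && stillImproving)
  finalVals <- vapply(pairEvals(w), `[[`, numeric(1), "value")

  new("Plan", weights = w, spots = problem$spots, strategy = strategy,
      diagnostics = list(iterations = totalIter, objective = fTrue,
                         converged = converged, history = history,
                         pairValues = finalVals))
}
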