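# Penalty objective terms in the usual TPS style: one-sided quadratic
# under/overdose penalties, a mean-dose penalty and quota-based DVH
# penalties. All terms are nonnegative and zero exactly when satisfied.

#' Construct an objective term
#'
#' Term kinds (dose `d` = `doseGy`, structure voxel doses `x_j`, `N` voxels):
#' * `min_dose`:  `sum_j max(0, d - x_j)^2 / N` (quadratic underdose penalty);
#' * `max_dose`:  `sum_j max(0, x_j - d)^2 / N` (quadratic overdose penalty);
#' * `mean_upper`: `max(0, mean(x) - d)^2`;
#' * `dvh_upper` (V(d) <= `volume` cc): quadratic push-down to level `d` of
#'   the lowest-dose voxels exceeding `d` beyond the allowed volume quota;
#' * `dvh_lower` (V(d) >= `volume` %): quadratic push-up to level `d` of the
#'   highest-dose deficient voxels needed to reach the quota.
#'
#' @param structure Structure name the term applies to.
#' @param kind One of `min_dose`, `max_dose`, `mean_upper`, `dvh_upper`,
#'   `dvh_lower`.
#' @param doseGy Dose level `d` (for `mean_upper`, the mean limit), `>= 0`.
#' @param volume Volume parameter: cc for `dvh_upper`, percent for
#'   `dvh_lower`; ignored otherwise.
#' @param weight Nonnegative term weight.
#' @return List of class `"ObjectiveTerm"`.
#' @export
objectiveTerm <- function(structure, kind, doseGy, volume = NA_real_, weight = 1) {
  kinds <- c("min_dose", "max_dose", "mean_upper", "dvh_upper", "dvh_lower")
  if (!kind %in% kinds) stop("unknown objective term kind '", kind, "'")
  stopifnot(weight >= 0, doseGy >= 0)
  structure(list(structure = structure, kind = kind, doseGy = doseGy,
                 volume = volume, weight = weight),
            class = "ObjectiveTerm")
}

# Core evaluation on the masked dose values; returns value and the gradient
# with respect to each masked voxel dose.
termEvalCore <- function(kind, level, volume, dm, voxcc) {
  N <- length(dm)
  g <- numeric(N)
  val <- 0
  if (kind == "min_dose") {
    diff <- pmax(0, level - dm)
    val <- sum(diff^2) / N
    g <- -2 * diff / N
  } else if (kind == "max_dose") {
    diff <- pmax(0, dm - level)
    val <- sum(diff^2) / N
    g <- 2 * diff / N
  } else if (kind == "mean_upper") {
    ex <- max(0, mean(dm) - level)
    val <- ex^2
    g[] <- 2 * ex / N
  } else if (kind == "dvh_upper") {
    quota <- floor(volume / voxcc + 1e-9)
    ex <- which(dm > level)
    if (length(ex) > quota) {
      o <- ex[order(dm[ex])]
      sel <- o[seq_len(length(ex) - quota)]
      d <- dm[sel] - level
      val <- sum(d^2) / N
      g[sel] <- 2 * d / N
    }
  } else if (kind == "dvh_lower") {
    nReq <- ceiling(volume / 100 * N - 1e-9)
    nHave <- sum(dm >= level)
    if (nHave < nReq) {
      defi <- which(dm < level)
      o <- defi[order(dm[defi], decreasing = TRUE)]
      sel <- o[seq_len(nReq - nHave)]
      d <- level - dm[sel]
      val <- sum(d^2) / N
      g[sel] <- -2 * d / N
    }
  } else stop("unknown objective term kind '", kind, "'")
  list(value = val, grad = g)
}

#' Objective term value and dose gradient
#'
#' @param term An [objectiveTerm()].
#' @param dose Numeric 3D dose grid (Gy-RBE).
#' @param mask Logical array on the dose grid; must be non-empty.
#' @param spacing Voxel spacing in mm.
#' @return `list(value, gradient)` where `gradient` is a numeric array on
#'   the dose grid (zero outside the mask), consistent with finite
#'   differences of the value.
#' @export
termValueAndGradient <- function(term, dose, mask, spacing) {
  stopifnot(inherits(term, "ObjectiveTerm"))
  if (!identical(dim(dose), dim(mask))) stop("dose and mask must share one grid")
  if (!any(mask)) stop("objective term evaluated on an empty mask")
  res <- termEvalCore(term$kind, term$doseGy, term$volume, dose[mask],
                      voxelVolumeCC(spacing))
  grad <- array(0, dim = dim(dose))
  grad[mask] <- res$grad
  list(value = res$value, gradient = grad)
}

# Resolved term: an ObjectiveTerm bound to voxel indices on a concrete grid.
resolveTerm <- function(term, maskIdx) {
  term$maskIdx <- maskIdx
  term
}

# Composite objective value (sum of weighted terms) on a dose vector;
# optionally accumulates the gradient into a full-length voxel vector.
compositeEval <- function(terms, doseVec, voxcc, gradient = FALSE) {
  val <- 0
  g <- if (gradient) numeric(length(doseVec)) else NULL
  for (tm in terms) {
    res <- termEvalCore(tm$kind, tm$doseGy, tm$volume, doseVec[tm$maskIdx], voxcc)
    val <- val + tm$weight * res$value
    if (gradient) {
      g[tm$maskIdx] <- g[tm$maskIdx] + tm$weight * res$grad
    }
  }
  list(value = val, grad = g)
}
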