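# Contour-ensemble algebra: union/intersection, voxel agreement maps,
# exact-level agreement substructures and the conservative combination.

#' Voxelwise union of binary masks
#' @param masks List of logical arrays on one grid (length `>= 1`).
#' @return Logical array, the voxelwise OR.
#' @export
maskUnion <- function(masks) {
  stopifnot(length(masks) >= 1L)
  stopIfNotGrid(masks)
  Reduce(`|`, masks)
}

#' Voxelwise intersection of binary masks
#' @param masks List of logical arrays on one grid (length `>= 1`).
#' @return Logical array, the voxelwise AND.
#' @export
maskIntersection <- function(masks) {
  stopifnot(length(masks) >= 1L)
  stopIfNotGrid(masks)
  Reduce(`&`, masks)
}

#' Voxel agreement map of a structure-set ensemble
#'
#' For every structure, the per-voxel fraction of ensemble sets that
#' classify the voxel as part of the structure: 1 where all sets agree,
#' `k/K` where `k` of `K` sets include the voxel, 0 outside the union.
#'
#' @param ensemble List of `>= 2` [StructureSet-class] objects sharing a grid
#'   and structure roster.
#' @return An [AgreementMap-class].
#' @export
agreementMap <- function(ensemble) {
  stopifnot(length(ensemble) >= 2L)
  K <- length(ensemble)
  roster <- structureNames(ensemble[[1]])
  for (s in ensemble[-1]) {
    missing <- setdiff(roster, structureNames(s))
    extra <- setdiff(structureNames(s), roster)
    if (length(missing) || length(extra)) {
      stop("ensemble structure rosters differ (missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "), ")")
    }
  }
  vals <- list()
  for (nm in roster) {
    acc <- getMask(ensemble[[1]], nm) + 0
    for (s in ensemble[-1]) acc <- acc + getMask(s, nm)
    vals[[nm]] <- acc / K
  }
  new("AgreementMap", values = vals, K = as.integer(K),
      spacing = voxelSpacing(ensemble[[1]]))
}

#' Exact-level substructure partition of an agreement map
#'
#' Partitions the ensemble union of each structure into exact agreement
#' levels: the level labelled `round(100 k / K)` percent contains exactly
#' the voxels included by `k` of the `K` sets (not a nested/cumulative
#' thresholding). For K = 3 the levels are 33, 67 and 100; a voxel included
#' by exactly two sets belongs to level 67 and only level 67. Level masks
#' are pairwise disjoint and their union is the ensemble union.
#'
#' @param agreement An [AgreementMap-class].
#' @param K Ensemble size; must equal the agreement map's `K`.
#' @return A [SubstructureSet-class].
#' @export
substructurePartition <- function(agreement, K = agreement@K) {
  stopifnot(is(agreement, "AgreementMap"))
  K <- as.integer(K)
  if (K != agreement@K) {
    stop("K (", K, ") must equal the agreement map ensemble size (", agreement@K, ")")
  }
  levels <- list()
  for (nm in names(agreement@values)) {
    counts <- round(agreement@values[[nm]] * K)
    if (any(abs(agreement@values[[nm]] * K - counts) > 1e-6) ||
        any(counts < 0 | counts > K)) {
      stop("agreement values for '", nm, "' are inconsistent with K = ", K)
    }
    lv <- list()
    for (k in seq_len(K)) {
      lv[[as.character(round(100 * k / K))]] <- array(counts == k, dim = dim(counts))
    }
    levels[[nm]] <- lv
  }
  new("SubstructureSet", levels = levels, K = K, spacing = agreement@spacing)
}

#' Conservative combination of a contour ensemble
#'
#' Combines the K propagated structure sets into one: organs at risk take
#' the union of the K masks; the target takes the intersection under a
#' stereotactic prescription (organ limits outrank coverage, so the smallest
#' plausible target is used with the largest plausible organs) and the union
#' under a coverage-first prescription. An empty target intersection is
#' allowed but flagged (attribute `emptyTarget` on the returned set);
#' optimization may still run with coverage terms skipped for empty masks.
#'
#' @param ensemble List of `>= 2` [StructureSet-class] objects with a shared
#'   roster.
#' @param priorityMode `"stereotactic"` or `"coverage"`; defaults to the
#'   ensemble's own mode.
#' @return A [StructureSet-class].
#' @export
conservativeCombination <- function(ensemble, priorityMode = NULL) {
  stopifnot(length(ensemble) >= 2L)
  if (is.null(priorityMode)) priorityMode <- priorityMode(ensemble[[1]])
  if (!priorityMode %in% c("stereotactic", "coverage")) {
    stop("priorityMode must be 'stereotactic' or 'coverage'")
  }
  am <- agreementMap(ensemble)  # validates the shared roster/grid
  roles <- structureRoles(ensemble[[1]])
  masks <- list()
  emptyTarget <- character()
  for (nm in names(am@values)) {
    ml <- lapply(ensemble, getMask, name = nm)
    if (roles[[nm]] == "target" && priorityMode == "stereotactic") {
      masks[[nm]] <- maskIntersection(ml)
      if (!any(masks[[nm]])) emptyTarget <- c(emptyTarget, nm)
    } else {
      masks[[nm]] <- maskUnion(ml)
    }
  }
  if (length(emptyTarget)) {
    warning("conservative combination produced an empty target intersection for: ",
            paste(emptyTarget, collapse = ", "))
  }
  out <- structureSet(masks, roles, priorityMode, voxelSpacing(ensemble[[1]]))
  attr(out, "emptyTarget") <- emptyTarget
  out
}

#' Volume of a binary mask in cubic centimetres
#' @param mask Logical array.
#' @param spacing Voxel spacing in mm (all `> 0`).
#' @return Volume in cc: voxel count times voxel volume.
#' @export
volumeCC <- function(mask, spacing) {
  stopifnot(all(spacing > 0))
  sum(mask) * voxelVolumeCC(spacing)
}
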