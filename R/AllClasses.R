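#' @import methods
#' @importFrom Matrix sparseMatrix crossprod readMM writeMM
#' @importClassesFrom Matrix dgCMatrix
NULL

#' StructureSet: named binary masks with clinical roles
#'
#' Container for a set of contoured structures on a common voxel grid. Each
#' structure is a logical mask with a role: `target` (CTV), `oar` (organ at
#' risk) or `external` (patient outline). A voxel may belong to several
#' structures; overlapping assignments are kept in all structures and handled
#' downstream by the optimizer. The `priorityMode` records whether the
#' prescription is stereotactic (OAR hard limits outrank target coverage, as
#' in hypofractionated abdominal treatments) or coverage-first (head and
#' neck).
#'
#' @slot masks Named list of logical 3D arrays sharing one grid.
#' @slot roles Named character vector (`target`/`oar`/`external`), aligned
#'   with `masks`.
#' @slot priorityMode `"stereotactic"` or `"coverage"`.
#' @slot spacing Voxel spacing in mm (length 3).
#' @export
setClass("StructureSet", representation(
  masks = "list", roles = "character", priorityMode = "character",
  spacing = "numeric"
))

setValidity("StructureSet", function(object) {
  msg <- character()
  if (length(object@masks) == 0L) msg <- c(msg, "at least one structure required")
  if (is.null(names(object@masks)) || anyDuplicated(names(object@masks))) {
    msg <- c(msg, "structure names must be unique and non-empty")
  }
  if (!identical(sort(names(object@masks)), sort(names(object@roles)))) {
    msg <- c(msg, "roles must be named for every structure")
  }
  if (!all(object@roles %in% c("target", "oar", "external"))) {
    msg <- c(msg, "roles must be one of target/oar/external")
  }
  dims <- lapply(object@masks, dim)
  if (length(dims) && !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    msg <- c(msg, "all masks must share one grid shape")
  }
  if (!any(object@roles == "target")) msg <- c(msg, "at least one target structure required")
  if (!object@priorityMode %in% c("stereotactic", "coverage")) {
    msg <- c(msg, "priorityMode must be 'stereotactic' or 'coverage'")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' Phantom: density grid plus ground-truth structures for one anatomy instance
#'
#' A synthetic stand-in for one planning or daily image: a relative stopping
#' power grid (dimensionless, water = 1) together with the "clinical"
#' structure set that is ground truth by construction. `fractionIndex` 0 is
#' the planning anatomy; daily anatomies carry the fraction number.
#'
#' @slot density Numeric 3D array of relative stopping power, all `>= 0`.
#' @slot structures A [StructureSet-class] on the same grid.
#' @slot spacing Voxel spacing in mm.
#' @slot fractionIndex Integer, 0 for the planning anatomy.
#' @slot template Template name (`"abdomen"` or `"head_neck"`).
#' @export
setClass("Phantom", representation(
  density = "array", structures = "StructureSet", spacing = "numeric",
  fractionIndex = "integer", template = "character"
))

setValidity("Phantom", function(object) {
  msg <- character()
  if (any(!is.finite(object@density)) || any(object@density < 0)) {
    msg <- c(msg, "density must be finite and >= 0 everywhere")
  }
  if (length(object@structures@masks) &&
      !identical(dim(object@density), dim(object@structures@masks[[1]]))) {
    msg <- c(msg, "structure masks must share the density grid shape")
  }
  tn <- names(object@structures@roles)[object@structures@roles == "target"]
  if (length(tn) && !any(vapply(tn, function(nm) any(object@structures@masks[[nm]]), logical(1)))) {
    msg <- c(msg, "target mask must be non-empty")
  }
  if (object@fractionIndex < 0L) msg <- c(msg, "fractionIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DisplacementField: per-voxel 3-vector displacement in mm
#'
#' Dense displacement field on a phantom grid. The warp convention is
#' pull-back: the warped image at voxel `x` samples the source image at
#' `x - d(x)`, so a uniform field of `+1` voxel shifts content by `+1` voxel
#' and the zero field is the identity warp.
#'
#' @slot vectors 4D numeric array, `dim = c(grid, 3)`, mm.
#' @slot spacing Voxel spacing in mm.
#' @export
setClass("DisplacementField", representation(vectors = "array", spacing = "numeric"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L) return("vectors must have dim c(grid, 3)")
  if (any(!is.finite(object@vectors))) return("displacement field must be finite everywhere")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) return("bad spacing")
  TRUE
})

#' AgreementMap: per-voxel classification frequency across a contour ensemble
#'
#' For each structure, the fraction of ensemble structure sets that contain
#' each voxel. For a K-set ensemble the values are in `{0, 1/K, ..., 1}`;
#' the value is 1 exactly on the ensemble intersection and positive exactly
#' on the ensemble union.
#'
#' @slot values Named list of numeric 3D arrays in `[0, 1]`.
#' @slot K Ensemble size.
#' @slot spacing Voxel spacing in mm.
#' @export
setClass("AgreementMap", representation(values = "list", K = "integer", spacing = "numeric"))

setValidity("AgreementMap", function(object) {
  if (object@K < 2L) return("K must be >= 2")
  for (v in object@values) {
    if (any(v < -1e-9 | v > 1 + 1e-9)) return("agreement values must lie in [0, 1]")
    kv <- v * object@K
    if (any(abs(kv - round(kv)) > 1e-6)) return("agreement values must be multiples of 1/K")
  }
  TRUE
})

#' SubstructureSet: exact-level partition of a contour ensemble union
#'
#' For each structure, one mask per agreement level: the level-`round(100k/K)`
#' mask contains exactly the voxels included by `k` of the `K` ensemble
#' contours. Levels are pairwise disjoint and their union is the ensemble
#' union (for K = 3 the levels are 33, 67 and 100).
#'
#' @slot levels Named list (per structure) of named lists (per percent level)
#'   of logical masks.
#' @slot K Ensemble size.
#' @slot spacing Voxel spacing in mm.
#' @export
setClass("SubstructureSet", representation(levels = "list", K = "integer", spacing = "numeric"))

#' SpotGrid: scanned proton spot roster for a set of beams
#'
#' One row per spot: the beam it belongs to, its lateral position in the
#' beam frame (mm) and its nominal range (mm water-equivalent depth of the
#' Bragg peak). Carries the beam configurations used for placement.
#'
#' @slot spots data.frame with columns `beam`, `u`, `v`, `range`.
#' @slot beams List of beam configurations (see [beamConfig()]).
#' @export
setClass("SpotGrid", representation(spots = "data.frame", beams = "list"))

setValidity("SpotGrid", function(object) {
  need <- c("beam", "u", "v", "range")
  if (!all(need %in% names(object@spots))) return("spots must have beam/u/v/range columns")
  if (nrow(object@spots) == 0L) return("spot roster is empty")
  if (any(object@spots$range <= 0)) return("spot ranges must be positive")
  TRUE
})

#' InfluenceMatrix: sparse spot-to-voxel dose mapping for one error scenario
#'
#' Sparse matrix of dose per unit spot weight per fraction (Gy-RBE),
#' `n_spots x n_voxels`, with the setup/range scenario it was computed for.
#' Entries below the configured sparsity floor are dropped at build time.
#'
#' @slot dose `dgCMatrix`, spots in rows, voxels (column-major grid order) in
#'   columns; all entries `>= 0`.
#' @slot scenario Scenario list (see [scenarioSet()]).
#' @slot gridDim Integer grid shape.
#' @slot spacing Voxel spacing in mm.
#' @export
setClass("InfluenceMatrix", representation(
  dose = "dgCMatrix", scenario = "list", gridDim = "integer", spacing = "numeric"
))

setValidity("InfluenceMatrix", function(object) {
  if (ncol(object@dose) != prod(object@gridDim)) return("dose columns must match grid size")
  if (length(object@dose@x) && min(object@dose@x) < 0) return("influence entries must be >= 0")
  TRUE
})

#' Plan: nonnegative spot weights with strategy provenance
#'
#' @slot weights Nonnegative spot weights, one per spot.
#' @slot spots The [SpotGrid-class] the weights refer to.
#' @slot strategy Strategy tag (`single_dir_k`, `multi_dir`, `conservative`,
#'   `probabilistic`, `reference`, `no_adaptation`, or `initial`).
#' @slot diagnostics Solver diagnostics (iterations, objective history,
#'   convergence flag).
#' @export
setClass("Plan", representation(
  weights = "numeric", spots = "SpotGrid", strategy = "character",
  diagnostics = "list"
))

setValidity("Plan", function(object) {
  if (any(!is.finite(object@weights))) return("weights must be finite")
  if (any(object@weights < -1e-12)) return("weights must be >= 0")
  if (length(object@weights) != nrow(object@spots@spots)) {
    return("weights length must equal the spot count")
  }
  TRUE
})
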