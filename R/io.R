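# Standard-format I/O: phantoms and masks as NIfTI (density float32, masks
# uint8, one file per structure, spacing in the header), sparse influence
# matrices as MatrixMarket, plans and manifests as JSON.

#' @importFrom RNifti asNifti writeNifti readNifti pixdim
#' @importFrom jsonlite write_json read_json
NULL

niftiWrite <- function(arr, spacing, file, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}

#' Write a phantom to a directory as NIfTI plus a JSON manifest
#'
#' Writes `density.nii.gz` (float32 relative stopping power), one
#' `mask_<structure>.nii.gz` per structure (uint8), and `phantom.json`
#' (roster, roles, priority mode, spacing, fraction index, template).
#'
#' @param phantom A [Phantom-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "Phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- voxelSpacing(phantom)
  niftiWrite(phantom@density, sp, file.path(dir, "density.nii.gz"), "float")
  ss <- phantom@structures
  for (nm in structureNames(ss)) {
    niftiWrite(getMask(ss, nm) + 0L, sp,
               file.path(dir, paste0("mask_", nm, ".nii.gz")), "uint8")
  }
  manifest <- list(
    template = phantom@template, fractionIndex = phantom@fractionIndex,
    gridShape = gridShape(phantom), spacingMM = sp,
    priorityMode = priorityMode(ss),
    structures = as.list(structureRoles(ss))
  )
  jsonlite::write_json(manifest, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom written by [writePhantom()]
#' @param dir Directory containing `density.nii.gz`, masks and `phantom.json`.
#' @return A [Phantom-class].
#' @export
readPhantom <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "phantom.json"))
  sp <- as.numeric(unlist(manifest$spacingMM))
  density <- array(as.numeric(RNifti::readNifti(file.path(dir, "density.nii.gz"))),
                   dim = as.integer(unlist(manifest$gridShape)))
  roles <- unlist(manifest$structures)
  masks <- lapply(names(roles), function(nm) {
    arr <- RNifti::readNifti(file.path(dir, paste0("mask_", nm, ".nii.gz")))
    array(as.numeric(arr) > 0.5, dim = dim(density))
  })
  names(masks) <- names(roles)
  ss <- structureSet(masks, roles, manifest$priorityMode, sp)
  new("Phantom", density = density, structures = ss, spacing = sp,
      fractionIndex = as.integer(manifest$fractionIndex),
      template = manifest$template)
}

#' Write an influence matrix (MatrixMarket plus JSON sidecar)
#'
#' @param influence An [InfluenceMatrix-class].
#' @param path Basename; writes `<path>.mtx` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeInfluence <- function(influence, path) {
  stopifnot(is(influence, "InfluenceMatrix"))
  Matrix::writeMM(influence@dose, paste0(path, ".mtx"))
  jsonlite::write_json(list(
    scenario = influence@scenario, gridShape = influence@gridDim,
    spacingMM = influence@spacing
  ), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an influence matrix written by [writeInfluence()]
#' @param path Basename used at write time.
#' @return An [InfluenceMatrix-class].
#' @export
readInfluence <- function(path) {
  mat <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  sc <- meta$scenario
  sc$setupShiftMM <- as.numeric(unlist(sc$setupShiftMM))
  new("InfluenceMatrix", dose = mat, scenario = sc,
      gridDim = as.integer(unlist(meta$gridShape)),
      spacing = as.numeric(unlist(meta$spacingMM)))
}

#' Serialize a plan to JSON
#'
#' Stores the spot weights, spot table, beam configurations, strategy tag
#' and solver diagnostics.
#'
#' @param plan A [Plan-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writePlan <- function(plan, file) {
  stopifnot(is(plan, "Plan"))
  jsonlite::write_json(list(
    strategy = plan@strategy,
    weights = plan@weights,
    spots = spotTable(plan@spots),
    beams = lapply(plan@spots@beams, unclass),
    diagnostics = plan@diagnostics[c("iterations", "objective", "converged")]
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a plan written by [writePlan()]
#' @param file JSON path.
#' @return A [Plan-class].
#' @export
readPlan <- function(file) {
  obj <- jsonlite::read_json(file)
  beams <- lapply(obj$beams, function(b) {
    beamConfig(unlist(b$direction),
               lateralSpacingMM = b$lateralSpacingMM,
               layerSpacingMM = b$layerSpacingMM,
               lateralSigmaMM = b$lateralSigmaMM,
               targetMarginMM = b$targetMarginMM)
  })
  spotDf <- do.call(rbind, lapply(obj$spots, function(row) {
    data.frame(beam = as.integer(row$beam), u = row$u, v = row$v,
               range = row$range)
  }))
  spots <- new("SpotGrid", spots = spotDf, beams = beams)
  new("Plan", weights = as.numeric(unlist(obj$weights)), spots = spots,
      strategy = obj$strategy, diagnostics = lapply(obj$diagnostics, unlist))
}

#' Write a dose grid as NIfTI
#' @param dose Numeric 3D array (Gy-RBE).
#' @param spacing Voxel spacing in mm.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @export
writeDose <- function(dose, spacing, file) {
  niftiWrite(dose, spacing, file, "float")
}
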