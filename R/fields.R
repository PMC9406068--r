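# Smooth random displacement fields and mask transport.

#' Construct a displacement field
#'
#' @param vectors 4D numeric array, `dim = c(grid, 3)`, displacement in mm.
#' @param spacing Voxel spacing in mm.
#' @return A [DisplacementField-class].
#' @export
displacementField <- function(vectors, spacing) {
  new("DisplacementField", vectors = vectors, spacing = as.numeric(spacing))
}

#' Zero displacement field
#' @param gridDim Grid shape.
#' @param spacing Voxel spacing (mm).
#' @export
zeroField <- function(gridDim, spacing) {
  displacementField(array(0, dim = c(gridDim, 3)), spacing)
}

#' Smooth zero-mean random displacement field
#'
#' Gaussian white noise per voxel and component, smoothed with a separable
#' Gaussian kernel of standard deviation `correlationLengthMM`, then
#' recentred and rescaled so each component has exactly zero mean and the
#' requested per-component standard deviation over the grid. Deterministic
#' given the seed.
#'
#' @param gridDim Grid shape (3 integers).
#' @param spacing Voxel spacing in mm.
#' @param amplitudeMM Target per-component standard deviation (mm, `>= 0`).
#' @param correlationLengthMM Smoothness scale (Gaussian kernel sigma, mm, `> 0`).
#' @param seed Integer seed.
#' @return A [DisplacementField-class].
#' @export
smoothRandomField <- function(gridDim, spacing, amplitudeMM, correlationLengthMM, seed) {
  stopifnot(amplitudeMM >= 0, correlationLengthMM > 0)
  gridDim <- as.integer(gridDim)
  vec <- array(0, dim = c(gridDim, 3))
  if (amplitudeMM > 0) {
    sigmaVox <- correlationLengthMM / spacing
    vec <- withSeed(seed, {
      out <- array(0, dim = c(gridDim, 3))
      for (comp in 1:3) {
        noise <- array(stats::rnorm(prod(gridDim)), dim = gridDim)
        sm <- smoothArrayGaussian(noise, sigmaVox)
        sm <- sm - mean(sm)
        s <- stats::sd(as.numeric(sm))
        if (s > 0) sm <- sm * (amplitudeMM / s)
        out[, , , comp] <- sm
      }
      out
    })
  }
  displacementField(vec, spacing)
}

# Continuous 1-based index coordinates sampled by the pull-back warp:
# sample position (mm) = voxel centre - displacement.
warpSampleCoords <- function(field) {
  d <- dim(field@vectors)[1:3]
  sp <- field@spacing
  cc <- axisCoords(d, sp)
  base <- list(
    outerSum3(cc[[1]], rep(0, d[2]), rep(0, d[3])),
    outerSum3(rep(0, d[1]), cc[[2]], rep(0, d[3])),
    outerSum3(rep(0, d[1]), rep(0, d[2]), cc[[3]])
  )
  lapply(1:3, function(ax) {
    (as.numeric(base[[ax]]) - as.numeric(field@vectors[, , , ax])) / sp[ax] + 0.5
  })
}

#' Warp a binary mask with a displacement field
#'
#' Level-set transport: the 0/1 mask is trilinearly interpolated at the
#' displaced sample positions and thresholded at 0.5. Sample positions
#' falling outside the grid read background. Exact integer-voxel
#' translations reproduce the integer-shifted mask.
#'
#' @param mask Logical 3D array.
#' @param field A [DisplacementField-class] on the same grid.
#' @param spacing Voxel spacing in mm (must match the field's).
#' @return Logical 3D array.
#' @export
warpMask <- function(mask, field, spacing = voxelSpacing(field)) {
  stopifnot(is(field, "DisplacementField"))
  if (!identical(dim(mask), dim(field@vectors)[1:3])) {
    stop("mask and displacement field must share one grid")
  }
  if (any(!is.finite(field@vectors))) stop("displacement field must be finite")
  co <- warpSampleCoords(field)
  vals <- trilinearSample(mask + 0, co[[1]], co[[2]], co[[3]], outside = 0)
  array(vals >= 0.5, dim = dim(mask))
}

# Warp a scalar grid (density) with the same pull-back convention.
warpScalar <- function(arr, field, outside = 0) {
  co <- warpSampleCoords(field)
  array(trilinearSample(arr, co[[1]], co[[2]], co[[3]], outside = outside), dim = dim(arr))
}

#' @rdname DisplacementField-class
#' @param x A `DisplacementField`.
#' @export
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)

#' @rdname DisplacementField-class
#' @export
setMethod("gridShape", "DisplacementField", function(x) dim(x@vectors)[1:3])

# Sum of displacement fields on one grid.
addFields <- function(...) {
  fl <- list(...)
  v <- fl[[1]]@vectors
  for (f in fl[-1]) v <- v + f@vectors
  displacementField(v, fl[[1]]@spacing)
}

# Negated field (approximate inverse for small smooth fields).
negateField <- function(field) displacementField(-field@vectors, field@spacing)
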