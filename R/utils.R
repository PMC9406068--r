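# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators are pure functions of seed.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Per-axis voxel-centre world coordinates (mm): world = (index - 0.5) * spacing.
axisCoords <- function(gridDim, spacing) {
  lapply(1:3, function(ax) (seq_len(gridDim[ax]) - 0.5) * spacing[ax])
}

# n x 3 matrix of voxel-centre coordinates in array (column-major) order.
voxelCenters <- function(gridDim, spacing) {
  cc <- axisCoords(gridDim, spacing)
  cbind(
    rep(cc[[1]], times = gridDim[2] * gridDim[3]),
    rep(rep(cc[[2]], each = gridDim[1]), times = gridDim[3]),
    rep(cc[[3]], each = gridDim[1] * gridDim[2])
  )
}

# A 3D array whose entry is a1[i] + a2[j] + a3[k]; used for separable linear
# functionals of voxel position (beam-frame coordinates).
outerSum3 <- function(a1, a2, a3) {
  d <- c(length(a1), length(a2), length(a3))
  arr <- array(a1, dim = d)
  arr <- arr + rep(rep(a2, each = d[1]), times = d[3])
  arr + rep(a3, each = d[1] * d[2])
}

# Trilinear interpolation of a 3D array at continuous 1-based index coordinates.
# Samples outside the grid contribute `outside`.
trilinearSample <- function(arr, ci, cj, ck, outside = 0) {
  d <- dim(arr)
  n <- length(ci)
  i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
  fi <- ci - i0; fj <- cj - j0; fk <- ck - k0
  out <- numeric(n)
  for (di in 0:1) {
    wi <- if (di == 1L) fi else 1 - fi
    ii <- i0 + di
    for (dj in 0:1) {
      wj <- if (dj == 1L) fj else 1 - fj
      jj <- j0 + dj
      for (dk in 0:1) {
        wk <- if (dk == 1L) fk else 1 - fk
        kk <- k0 + dk
        w <- wi * wj * wk
        inside <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
        v <- rep(outside, n)
        if (any(inside)) {
          idx <- ii[inside] + (jj[inside] - 1) * d[1] + (kk[inside] - 1) * d[1] * d[2]
          v[inside] <- arr[idx]
        }
        out <- out + w * v
      }
    }
  }
  out
}

# Apply a linear operator K (n_ax x n_ax) along axis `ax` of a 3D array.
applyAlongAxis <- function(arr, ax, K) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = d[ax])
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

# Dense 1D Gaussian smoothing operator with edge renormalisation.
gaussOperator <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigmaVox))
  offs <- seq(-half, half)
  k <- exp(-offs^2 / (2 * sigmaVox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

# Separable Gaussian smoothing of a 3D array; sigma given per axis in voxels.
smoothArrayGaussian <- function(arr, sigmaVox) {
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0) {
      arr <- applyAlongAxis(arr, ax, gaussOperator(dim(arr)[ax], sigmaVox[ax]))
    }
  }
  arr
}

# Binary dilation by a physical radius (mm): union of integer-offset shifts
# whose world displacement lies within the radius.
dilateMask <- function(mask, spacing, marginMM) {
  if (marginMM <= 0) return(mask)
  d <- dim(mask)
  r <- pmax(0L, floor(marginMM / spacing))
  out <- mask
  for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
    if (di == 0 && dj == 0 && dk == 0) next
    if ((di * spacing[1])^2 + (dj * spacing[2])^2 + (dk * spacing[3])^2 > marginMM^2) next
    out <- out | shiftArray(mask, c(di, dj, dk))
  }
  out
}

# Shift a 3D array by an integer voxel offset, padding with `fill`.
shiftArray <- function(arr, off, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= d[ax] || -o >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b Logical arrays on the same grid.
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`; 1 if both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Centroid of a mask in world coordinates (mm).
maskCentroid <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute centroid of an empty mask")
  (colMeans(idx) - 0.5) * spacing
}

voxelVolumeCC <- function(spacing) prod(spacing) / 1000

stopIfNotGrid <- function(masks) {
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("masks do not share a common grid shape")
  }
  invisible(TRUE)
}
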