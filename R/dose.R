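# Simplified spot-scanning proton dose model. Depth dose is an analytic
# Bragg-peak shape in water-equivalent depth (WED); lateral spread is a
# single Gaussian in the beam frame. Spot-by-voxel dose per unit weight is
# assembled into sparse influence matrices, one per setup/range error
# scenario.

#' Beam configuration
#'
#' @param direction Beam travel direction (3-vector; normalised internally).
#' @param lateralSpacingMM Spot lattice spacing in the beam frame (mm, > 0).
#' @param layerSpacingMM Energy-layer spacing in WED (mm, > 0).
#' @param lateralSigmaMM Lateral Gaussian sigma of a single spot (mm, > 0).
#' @param targetMarginMM Geometric margin around the target used for spot
#'   placement (mm, >= 0).
#' @return A validated list of class `"BeamConfig"`.
#' @export
beamConfig <- function(direction, lateralSpacingMM = 10, layerSpacingMM = 8,
                       lateralSigmaMM = 8, targetMarginMM = 8) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("beam direction must be a nonzero 3-vector")
  stopifnot(lateralSpacingMM > 0, layerSpacingMM > 0, lateralSigmaMM > 0,
            targetMarginMM >= 0)
  structure(list(
    direction = direction / nrm, lateralSpacingMM = lateralSpacingMM,
    layerSpacingMM = layerSpacingMM, lateralSigmaMM = lateralSigmaMM,
    targetMarginMM = targetMarginMM
  ), class = "BeamConfig")
}

#' Default beam arrangement for a template
#'
#' Three axis-aligned beams for the abdominal template (two lateral, one
#' anterior) and four for head and neck (two lateral, anterior, posterior),
#' with spot spacings sized to the template's target volume.
#'
#' @param template `"abdomen"` or `"head_neck"`.
#' @return List of [beamConfig()] objects.
#' @export
templateBeams <- function(template) {
  if (template == "abdomen") {
    list(
      beamConfig(c(1, 0, 0)),
      beamConfig(c(-1, 0, 0)),
      beamConfig(c(0, -1, 0))
    )
  } else if (template == "head_neck") {
    hn <- function(d) beamConfig(d, lateralSpacingMM = 14, layerSpacingMM = 10,
                                 lateralSigmaMM = 9)
    list(hn(c(1, 0, 0)), hn(c(-1, 0, 0)), hn(c(0, -1, 0)), hn(c(0, 1, 0)))
  } else stop("unknown template '", template, "'")
}

# Orthonormal lateral frame (u, v) perpendicular to the beam direction.
beamFrame <- function(direction) {
  a <- c(0, 0, 1)
  if (abs(sum(a * direction)) > 0.9) a <- c(0, 1, 0)
  u <- c(direction[2] * a[3] - direction[3] * a[2],
         direction[3] * a[1] - direction[1] * a[3],
         direction[1] * a[2] - direction[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(direction[2] * u[3] - direction[3] * u[2],
         direction[3] * u[1] - direction[1] * u[3],
         direction[1] * u[2] - direction[2] * u[1])
  list(u = u, v = v)
}

axisAlignedBeam <- function(direction) {
  hits <- which(abs(abs(direction) - 1) < 1e-12)
  if (length(hits) == 1L && sum(abs(direction)) - 1 < 1e-12) {
    list(axis = hits, sign = sign(direction[hits]))
  } else NULL
}

# Cumulative WED operator along one axis: entries in mm water-equivalent.
wedOperator <- function(n, stepMM, forward = TRUE) {
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (forward) {
      if (i > 1) L[i, 1:(i - 1)] <- stepMM
    } else {
      if (i < n) L[i, (i + 1):n] <- stepMM
    }
    L[i, i] <- stepMM / 2
  }
  L
}

# WED at every voxel centre for one beam on one phantom. Axis-aligned beams
# use an exact cumulative-sum operator; oblique beams fall back to ray
# marching with trilinear density sampling.
wedGridForBeam <- function(phantom, direction, stepMM = NULL) {
  gd <- gridShape(phantom); sp <- voxelSpacing(phantom)
  ax <- axisAlignedBeam(direction)
  if (!is.null(ax)) {
    return(applyAlongAxis(phantom@density, ax$axis,
                          wedOperator(gd[ax$axis], sp[ax$axis], forward = ax$sign > 0)))
  }
  if (is.null(stepMM)) stepMM <- min(sp) / 2
  extent <- gd * sp
  maxLen <- sqrt(sum(extent^2))
  K <- ceiling(maxLen / stepMM)
  cc <- axisCoords(gd, sp)
  X <- list(outerSum3(cc[[1]], rep(0, gd[2]), rep(0, gd[3])),
            outerSum3(rep(0, gd[1]), cc[[2]], rep(0, gd[3])),
            outerSum3(rep(0, gd[1]), rep(0, gd[2]), cc[[3]]))
  wed <- numeric(prod(gd))
  for (k in seq_len(K)) {
    t <- (k - 0.5) * stepMM
    px <- as.numeric(X[[1]]) - t * direction[1]
    py <- as.numeric(X[[2]]) - t * direction[2]
    pz <- as.numeric(X[[3]]) - t * direction[3]
    inside <- px >= 0 & px <= extent[1] & py >= 0 & py <= extent[2] &
      pz >= 0 & pz <= extent[3]
    if (!any(inside)) break
    rho <- numeric(length(px))
    ci <- pmin(pmax(px[inside] / sp[1] + 0.5, 1), gd[1])
    cj <- pmin(pmax(py[inside] / sp[2] + 0.5, 1), gd[2])
    ck <- pmin(pmax(pz[inside] / sp[3] + 0.5, 1), gd[3])
    rho[inside] <- trilinearSample(phantom@density, ci, cj, ck, outside = 0)
    wed <- wed + rho * stepMM
  }
  array(wed, dim = gd)
}

#' Water-equivalent depth profile along a ray
#'
#' Marches from an entry point along a direction, accumulating relative
#' stopping power times path length. In a uniform medium of density rho the
#' profile is `WED(s) = rho * s`.
#'
#' @param phantom A [Phantom-class].
#' @param entryMM Ray entry point (mm, world coordinates).
#' @param direction Travel direction (normalised internally).
#' @param stepMM Integration step (mm).
#' @return data.frame with columns `distanceMM` (path length at sample
#'   midpoints' far edge) and `wedMM` (monotone non-decreasing).
#' @export
waterEquivalentDepth <- function(phantom, entryMM, direction, stepMM = NULL) {
  stopifnot(is(phantom, "Phantom"))
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  sp <- voxelSpacing(phantom); gd <- gridShape(phantom)
  if (is.null(stepMM)) stepMM <- min(sp) / 4
  extent <- gd * sp
  maxLen <- sqrt(sum(extent^2)) * 1.5
  K <- ceiling(maxLen / stepMM)
  t <- (seq_len(K) - 0.5) * stepMM
  px <- entryMM[1] + t * direction[1]
  py <- entryMM[2] + t * direction[2]
  pz <- entryMM[3] + t * direction[3]
  inside <- px >= 0 & px <= extent[1] & py >= 0 & py <= extent[2] &
    pz >= 0 & pz <= extent[3]
  if (!any(inside)) stop("ray does not intersect the phantom grid")
  rho <- numeric(K)
  ci <- pmin(pmax(px[inside] / sp[1] + 0.5, 1), gd[1])
  cj <- pmin(pmax(py[inside] / sp[2] + 0.5, 1), gd[2])
  ck <- pmin(pmax(pz[inside] / sp[3] + 0.5, 1), gd[3])
  rho[inside] <- trilinearSample(phantom@density, ci, cj, ck, outside = 0)
  data.frame(distanceMM = seq_len(K) * stepMM, wedMM = cumsum(rho * stepMM))
}

#' Analytic Bragg depth-dose curve
#'
#' Relative dose (peak approximately 1) as a function of water-equivalent
#' depth for a pencil beam with a given nominal range. The shape is an
#' asymmetric Gaussian peak at the nominal range (broad proximal shoulder,
#' sharp distal falloff) on top of a logistic entrance plateau: single
#' global maximum at the nominal range, entrance value about 35% of peak,
#' and dose below 1% of peak beyond 1.05 times the range.
#'
#' @param wedMM Water-equivalent depth(s) in mm (vectorised).
#' @param nominalRangeMM Bragg-peak position in mm WED (`> 0`).
#' @return Relative dose, same length as `wedMM`.
#' @export
braggCurve <- function(wedMM, nominalRangeMM) {
  stopifnot(nominalRangeMM > 0)
  R <- nominalRangeMM
  sig <- ifelse(wedMM < R, 0.07 * R, 0.012 * R)
  peak <- exp(-(wedMM - R)^2 / (2 * sig^2))
  z <- (wedMM - 0.95 * R) / (0.01 * R)
  entrance <- 0.35 / (1 + exp(pmin(z, 700)))
  peak + entrance
}

#' Setup/range error scenario set
#'
#' Default robustness model: the nominal scenario, six axis-aligned setup
#' shifts of the given magnitude, and two range scalings (1 +/- fraction),
#' nine scenarios in total. With `crossProduct = TRUE` the full product of
#' the seven shift states and three range states (21 scenarios) is
#' returned. Zero magnitudes collapse to the nominal scenario alone.
#'
#' @param setupMagnitudeMM Setup shift magnitude (mm, `>= 0`).
#' @param rangeFraction Relative range uncertainty (`>= 0`), e.g. 0.03.
#' @param crossProduct Combine shifts and range scalings multiplicatively.
#' @return List of scenarios: `list(setupShiftMM, rangeScale, label)`.
#' @export
scenarioSet <- function(setupMagnitudeMM = 3, rangeFraction = 0.03,
                        crossProduct = FALSE) {
  stopifnot(setupMagnitudeMM >= 0, rangeFraction >= 0)
  shifts <- list(c(0, 0, 0))
  shiftLabels <- "s0"
  if (setupMagnitudeMM > 0) {
    for (ax in 1:3) for (sgn in c(1, -1)) {
      s <- c(0, 0, 0); s[ax] <- sgn * setupMagnitudeMM
      shifts <- c(shifts, list(s))
      shiftLabels <- c(shiftLabels,
                       sprintf("%s%+g", c("x", "y", "z")[ax], sgn * setupMagnitudeMM))
    }
  }
  scales <- 1
  scaleLabels <- "r0"
  if (rangeFraction > 0) {
    scales <- c(scales, 1 - rangeFraction, 1 + rangeFraction)
    scaleLabels <- c(scaleLabels, sprintf("r%+g%%", c(-1, 1) * 100 * rangeFraction))
  }
  scen <- function(shift, scale, label) {
    list(setupShiftMM = shift, rangeScale = scale, label = label)
  }
  out <- list(scen(c(0, 0, 0), 1, "nominal"))
  if (crossProduct) {
    for (i in seq_along(shifts)) for (j in seq_along(scales)) {
      if (i == 1L && j == 1L) next
      out <- c(out, list(scen(shifts[[i]], scales[j],
                              paste(shiftLabels[i], scaleLabels[j], sep = "_"))))
    }
  } else {
    for (i in seq_along(shifts)[-1]) {
      out <- c(out, list(scen(shifts[[i]], 1, shiftLabels[i])))
    }
    for (j in seq_along(scales)[-1]) {
      out <- c(out, list(scen(c(0, 0, 0), scales[j], scaleLabels[j])))
    }
  }
  out
}

nominalScenario <- function() list(setupShiftMM = c(0, 0, 0), rangeScale = 1,
                                   label = "nominal")

#' Place scanning spots to cover the target
#'
#' For each beam, projects the target (union of target-role masks, dilated
#' by the beam's margin) into the beam frame, lays a lateral/energy-layer
#' lattice over it at the configured spacings, and keeps exactly the lattice
#' cells that are nearest to at least one target voxel. Every target voxel
#' is therefore within half a lattice spacing of a spot laterally and half a
#' layer spacing in WED.
#'
#' @param phantom The planning [Phantom-class].
#' @param beams List of [beamConfig()] objects.
#' @param targetNames Structures to cover; default all target-role masks.
#' @return A [SpotGrid-class].
#' @export
placeSpots <- function(phantom, beams, targetNames = NULL) {
  stopifnot(is(phantom, "Phantom"), length(beams) >= 1L)
  ss <- phantom@structures
  if (is.null(targetNames)) {
    targetNames <- names(ss@masks)[structureRoles(ss) == "target"]
  }
  target <- maskUnion(lapply(targetNames, getMask, x = ss))
  if (!any(target)) stop("cannot place spots: target is empty")
  sp <- voxelSpacing(phantom); gd <- gridShape(phantom)
  cc <- axisCoords(gd, sp)
  rows <- list()
  for (b in seq_along(beams)) {
    bc <- beams[[b]]
    dil <- dilateMask(target, sp, bc$targetMarginMM)
    wedG <- wedGridForBeam(phantom, bc$direction)
    fr <- beamFrame(bc$direction)
    idx <- which(dil, arr.ind = TRUE)
    pos <- sweep(idx - 0.5, 2, sp, `*`)
    lu <- as.numeric(pos %*% fr$u)
    lv <- as.numeric(pos %*% fr$v)
    wed <- wedG[dil]
    u0 <- min(lu); v0 <- min(lv); w0 <- min(wed)
    iu <- round((lu - u0) / bc$lateralSpacingMM)
    iv <- round((lv - v0) / bc$lateralSpacingMM)
    il <- round((wed - w0) / bc$layerSpacingMM)
    key <- paste(iu, iv, il)
    keep <- !duplicated(key)
    rows[[b]] <- data.frame(
      beam = b,
      u = u0 + iu[keep] * bc$lateralSpacingMM,
      v = v0 + iv[keep] * bc$lateralSpacingMM,
      range = pmax(w0 + il[keep] * bc$layerSpacingMM, bc$layerSpacingMM / 2)
    )
  }
  spots <- do.call(rbind, rows)
  new("SpotGrid", spots = spots, beams = beams)
}

#' Build the sparse influence matrix for one error scenario
#'
#' Dose per unit spot weight per fraction: for each spot, the analytic
#' Bragg curve evaluated at `rangeScale * WED` of the voxel position
#' displaced by the setup shift, times a lateral Gaussian in the beam
#' frame. Entries below `floorFrac` of the spot's maximum are dropped
#' (sparsity floor); each spot retains at least its maximum entry.
#'
#' @param phantom A [Phantom-class] (planning or daily).
#' @param spots A [SpotGrid-class] placed on the planning target.
#' @param scenario One element of [scenarioSet()]; `NULL` means nominal.
#' @param floorFrac Sparsity floor as a fraction of each spot's maximum.
#' @param sigmaWindow Lateral window half-width in units of the spot sigma.
#' @return An [InfluenceMatrix-class].
#' @export
buildInfluence <- function(phantom, spots, scenario = NULL,
                           floorFrac = 0.01, sigmaWindow = 3) {
  stopifnot(is(phantom, "Phantom"), is(spots, "SpotGrid"))
  if (is.null(scenario)) scenario <- nominalScenario()
  shift <- scenario$setupShiftMM
  rs <- scenario$rangeScale
  gd <- gridShape(phantom); sp <- voxelSpacing(phantom)
  nvox <- prod(gd)
  st <- spots@spots
  cc <- axisCoords(gd, sp)
  iAll <- jAll <- xAll <- vector("list", nrow(st))
  for (b in seq_along(spots@beams)) {
    bc <- spots@beams[[b]]
    inBeam <- which(st$beam == b)
    if (!length(inBeam)) next
    wedG <- wedGridForBeam(phantom, bc$direction)
    # WED and lateral coordinates evaluated at x + setup shift
    if (all(shift == 0)) {
      wedS <- as.numeric(wedG)
    } else {
      ci <- (rep(cc[[1]], times = gd[2] * gd[3]) + shift[1]) / sp[1] + 0.5
      cj <- (rep(rep(cc[[2]], each = gd[1]), times = gd[3]) + shift[2]) / sp[2] + 0.5
      ck <- (rep(cc[[3]], each = gd[1] * gd[2]) + shift[3]) / sp[3] + 0.5
      wedS <- trilinearSample(wedG, ci, cj, ck, outside = 1e6)
    }
    fr <- beamFrame(bc$direction)
    sConst <- sum(shift * fr$u)
    tConst <- sum(shift * fr$v)
    lu <- as.numeric(outerSum3(cc[[1]] * fr$u[1], cc[[2]] * fr$u[2],
                               cc[[3]] * fr$u[3])) + sConst
    lv <- as.numeric(outerSum3(cc[[1]] * fr$v[1], cc[[2]] * fr$v[2],
                               cc[[3]] * fr$v[3])) + tConst
    ord <- order(lu)
    luS <- lu[ord]
    W <- sigmaWindow * bc$lateralSigmaMM
    twoSig2 <- 2 * bc$lateralSigmaMM^2
    for (s in inBeam) {
      pu <- st$u[s]; pv <- st$v[s]; R <- st$range[s]
      win <- findInterval(c(pu - W, pu + W), luS)
      if (win[2] <= win[1]) next
      cand <- ord[(win[1] + 1):win[2]]
      dv <- lv[cand] - pv
      cand <- cand[abs(dv) <= W]
      if (!length(cand)) next
      du <- lu[cand] - pu
      dv <- lv[cand] - pv
      vals <- exp(-(du^2 + dv^2) / twoSig2) * braggCurve(rs * wedS[cand], R)
      mx <- max(vals)
      if (mx <= 0) next
      keep <- vals >= floorFrac * mx
      iAll[[s]] <- rep.int(s, sum(keep))
      jAll[[s]] <- cand[keep]
      xAll[[s]] <- vals[keep]
    }
  }
  mat <- Matrix::sparseMatrix(
    i = unlist(iAll), j = unlist(jAll), x = unlist(xAll),
    dims = c(nrow(st), nvox)
  )
  new("InfluenceMatrix", dose = methods::as(mat, "CsparseMatrix"),
      scenario = scenario, gridDim = as.integer(gd), spacing = sp)
}

#' Compute the dose grid delivered by a weighted plan
#'
#' Dose is exactly linear in the spot weights:
#' `dose = t(influence) %*% weights * nFractions` (Gy-RBE per course for the
#' default per-fraction influence entries).
#'
#' @param influence An [InfluenceMatrix-class].
#' @param weights Nonnegative spot weights (length = spot count).
#' @param nFractions Number of fractions the plan is delivered in.
#' @return Numeric 3D dose array on the influence grid.
#' @export
computeDose <- function(influence, weights, nFractions = 1) {
  stopifnot(is(influence, "InfluenceMatrix"))
  if (length(weights) != nrow(influence@dose)) {
    stop("weights length (", length(weights), ") must equal the spot count (",
         nrow(influence@dose), ")")
  }
  if (any(weights < -1e-9)) stop("spot weights must be >= 0")
  weights <- pmax(0, weights)
  d <- as.numeric(Matrix::crossprod(influence@dose, weights)) * nFractions
  array(d, dim = influence@gridDim)
}
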