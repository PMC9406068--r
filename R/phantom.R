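# Synthetic phantom generation: analytic anatomy templates standing in for
# planning/daily images, plus per-fraction anatomical change.

AIR_DENSITY <- 0.001

templateBoxMM <- function(template) {
  switch(template,
    abdomen   = c(240, 240, 240),
    head_neck = c(192, 192, 192),
    stop("unknown template '", template, "'; use 'abdomen' or 'head_neck'")
  )
}

templatePriorityMode <- function(template) {
  switch(template, abdomen = "stereotactic", head_neck = "coverage")
}

# Analytic organ geometry (mm, world coordinates). Shapes are ellipsoids,
# z-axis cylinders and paired ellipsoids; `subtract`/`union` reference
# previously defined structures (e.g. liver excludes the CTV, mirroring the
# clinical "liver minus GTV" evaluation volume).
defaultOrganGeometry <- function(template) {
  if (template == "abdomen") {
    list(
      list(name = "external",    role = "external", type = "ellipsoid",
           center = c(120, 120, 120), radii = c(112, 102, 112), density = 1.00),
      list(name = "ctv",         role = "target",   type = "ellipsoid",
           center = c(116, 124, 112), radii = c(25, 25, 24), density = 1.02),
      list(name = "stomach",     role = "oar",      type = "ellipsoid",
           center = c(64, 146, 132),  radii = c(26, 20, 24), density = 1.00),
      list(name = "small_bowel", role = "oar",      type = "ellipsoid",
           center = c(122, 166, 86),  radii = c(30, 24, 26), density = 1.00),
      list(name = "large_bowel", role = "oar",      type = "ellipsoid",
           center = c(174, 138, 96),  radii = c(22, 20, 30), density = 1.00),
      list(name = "duodenum",    role = "oar",      type = "ellipsoid",
           center = c(152, 124, 112), radii = c(12, 14, 20), density = 1.00),
      list(name = "spinal_cord", role = "oar",      type = "cylinderZ",
           center = c(120, 52), radius = 8, zRange = c(30, 210), density = 1.04),
      list(name = "kidneys",     role = "oar",      type = "pair",
           centers = list(c(66, 86, 96), c(174, 86, 96)), radii = c(16, 14, 22),
           density = 1.03),
      list(name = "liver",       role = "oar",      type = "ellipsoid",
           center = c(146, 114, 132), radii = c(76, 66, 64), density = 1.05,
           subtract = c("ctv", "duodenum"))
    )
  } else {
    list(
      list(name = "external",     role = "external", type = "ellipsoid",
           center = c(96, 96, 96), radii = c(70, 80, 88), density = 1.00),
      list(name = "ctv_high",     role = "target",   type = "ellipsoid",
           center = c(96, 110, 90), radii = c(29, 27, 25), density = 1.02),
      list(name = "ctv_low",      role = "target",   type = "ellipsoid",
           center = c(96, 112, 92), radii = c(44, 36, 38), density = 1.01,
           union = "ctv_high"),
      list(name = "brainstem",    role = "oar",      type = "ellipsoid",
           center = c(96, 60, 140), radii = c(10, 10, 24), density = 1.04),
      list(name = "spinal_cord",  role = "oar",      type = "cylinderZ",
           center = c(96, 54), radius = 7, zRange = c(20, 112), density = 1.04),
      list(name = "constrictors", role = "oar",      type = "ellipsoid",
           center = c(96, 68, 88), radii = c(16, 9, 32), density = 1.00),
      list(name = "larynx",       role = "oar",      type = "ellipsoid",
           center = c(96, 128, 52), radii = c(14, 13, 16), density = 0.95),
      list(name = "parotids",     role = "oar",      type = "pair",
           centers = list(c(44, 100, 104), c(148, 100, 104)), radii = c(12, 16, 20),
           density = 1.00)
    )
  }
}

#' Phantom specification
#'
#' Parameter bundle describing one synthetic anatomy: grid, template and
#' analytic organ geometry. Defaults give an abdominal-stereotactic or a
#' head-and-neck-like anatomy whose structure roster matches the template's
#' clinical constraint set, with a CTV volume in the clinically reported
#' range. Spacing defaults to the template's physical box divided by the
#' grid shape, so geometry is grid-resolution independent.
#'
#' @param template `"abdomen"` or `"head_neck"`.
#' @param gridShape Voxels per axis (3 integers, all `>= 16`).
#' @param spacingMM Voxel size per axis in mm; default `box / gridShape`.
#' @param organGeometry Analytic shape list; default per template.
#' @param densityBackground Relative stopping power of unclassified tissue
#'   inside the external contour.
#' @param seed Integer seed, used for the randomised geometry jitter.
#' @param jitterSdMM SD of a per-shape random centre displacement (mm) used
#'   to produce distinct phantoms of one template; 0 disables it.
#' @param radiusJitterFrac Relative SD of a per-axis radius perturbation.
#' @return A validated list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(template = c("abdomen", "head_neck"),
                        gridShape = c(48L, 48L, 48L),
                        spacingMM = NULL,
                        organGeometry = NULL,
                        densityBackground = 1.0,
                        seed = 1L,
                        jitterSdMM = 0,
                        radiusJitterFrac = 0) {
  template <- match.arg(template)
  gridShape <- as.integer(rep_len(gridShape, 3L))
  if (any(gridShape < 16L)) stop("gridShape must be >= 16 along every axis")
  box <- templateBoxMM(template)
  if (is.null(spacingMM)) spacingMM <- box / gridShape
  spacingMM <- as.numeric(rep_len(spacingMM, 3L))
  if (any(spacingMM <= 0)) stop("spacingMM must be positive")
  if (is.null(organGeometry)) organGeometry <- defaultOrganGeometry(template)
  extent <- gridShape * spacingMM
  if (jitterSdMM > 0 || radiusJitterFrac > 0) {
    organGeometry <- jitterGeometry(organGeometry, seed, jitterSdMM,
                                    radiusJitterFrac, extent)
  }
  for (g in organGeometry) {
    bb <- shapeBoundingBox(g)
    if (any(bb$lo < 0) || any(bb$hi > extent)) {
      stop("organ shape '", g$name, "' does not lie inside the grid (",
           paste(round(extent, 1), collapse = "x"), " mm)")
    }
  }
  if (densityBackground < 0) stop("densityBackground must be >= 0")
  structure(list(
    template = template, gridShape = gridShape, spacingMM = spacingMM,
    organGeometry = organGeometry, densityBackground = densityBackground,
    seed = as.integer(seed)
  ), class = "PhantomSpec")
}

# Randomised per-shape perturbation of the template geometry, clamped so
# every shape stays inside the grid. The external contour is left in place
# (only its radii vary) so organs keep a plausible frame.
jitterGeometry <- function(geom, seed, jitterSdMM, radiusJitterFrac, extent) {
  withSeed(seed, {
    for (i in seq_along(geom)) {
      g <- geom[[i]]
      rj <- function(r) {
        fac <- 1 + pmin(pmax(stats::rnorm(length(r), sd = radiusJitterFrac),
                             -2 * radiusJitterFrac), 2 * radiusJitterFrac)
        pmin(r * fac, extent[seq_along(r)] / 2 - 1)  # shape must fit the grid
      }
      shiftOf <- function() stats::rnorm(3, sd = jitterSdMM)
      if (g$type == "ellipsoid") {
        if (radiusJitterFrac > 0) g$radii <- rj(g$radii)
        if (jitterSdMM > 0 && g$name != "external") g$center <- g$center + shiftOf()
        g$center <- pmin(pmax(g$center, g$radii + 0.5), extent - g$radii - 0.5)
      } else if (g$type == "cylinderZ") {
        if (radiusJitterFrac > 0) g$radius <- rj(g$radius)
        if (jitterSdMM > 0) g$center <- g$center + shiftOf()[1:2]
        g$center <- pmin(pmax(g$center, g$radius + 0.5),
                         extent[1:2] - g$radius - 0.5)
        g$zRange <- pmin(pmax(g$zRange, 0.5), extent[3] - 0.5)
      } else if (g$type == "pair") {
        if (radiusJitterFrac > 0) g$radii <- rj(g$radii)
        for (k in seq_along(g$centers)) {
          if (jitterSdMM > 0) g$centers[[k]] <- g$centers[[k]] + shiftOf()
          g$centers[[k]] <- pmin(pmax(g$centers[[k]], g$radii + 0.5),
                                 extent - g$radii - 0.5)
        }
      }
      geom[[i]] <- g
    }
    geom
  })
}

shapeBoundingBox <- function(g) {
  if (g$type == "ellipsoid") {
    list(lo = g$center - g$radii, hi = g$center + g$radii)
  } else if (g$type == "cylinderZ") {
    list(lo = c(g$center - g$radius, g$zRange[1]),
         hi = c(g$center + g$radius, g$zRange[2]))
  } else if (g$type == "pair") {
    los <- sapply(g$centers, function(ct) ct - g$radii)
    his <- sapply(g$centers, function(ct) ct + g$radii)
    list(lo = apply(los, 1, min), hi = apply(his, 1, max))
  } else stop("unknown shape type '", g$type, "'")
}

rasterizeShape <- function(g, gridDim, spacing) {
  cc <- axisCoords(gridDim, spacing)
  ellipsoid <- function(center, radii) {
    q <- outerSum3(((cc[[1]] - center[1]) / radii[1])^2,
                   ((cc[[2]] - center[2]) / radii[2])^2,
                   ((cc[[3]] - center[3]) / radii[3])^2)
    q <= 1
  }
  if (g$type == "ellipsoid") {
    ellipsoid(g$center, g$radii)
  } else if (g$type == "cylinderZ") {
    q <- outerSum3(((cc[[1]] - g$center[1]) / g$radius)^2,
                   ((cc[[2]] - g$center[2]) / g$radius)^2,
                   rep(0, gridDim[3]))
    inz <- cc[[3]] >= g$zRange[1] & cc[[3]] <= g$zRange[2]
    (q <= 1) & rep(inz, each = gridDim[1] * gridDim[2])
  } else if (g$type == "pair") {
    m <- ellipsoid(g$centers[[1]], g$radii)
    m | ellipsoid(g$centers[[2]], g$radii)
  } else stop("unknown shape type '", g$type, "'")
}

#' Construct a StructureSet
#'
#' @param masks Named list of logical masks on one grid.
#' @param roles Named character vector of roles (`target`/`oar`/`external`).
#' @param priorityMode `"stereotactic"` or `"coverage"`.
#' @param spacing Voxel spacing in mm.
#' @return A [StructureSet-class].
#' @export
structureSet <- function(masks, roles, priorityMode, spacing) {
  new("StructureSet", masks = masks, roles = roles[names(masks)],
      priorityMode = priorityMode, spacing = as.numeric(spacing))
}

#' Generate a planning phantom from a specification
#'
#' Rasterizes the template's analytic organ geometry onto the voxel grid and
#' assembles the relative stopping power grid: air outside the external
#' contour, background soft tissue inside, with mild per-organ density
#' contrast. The resulting structure set is the ground-truth ("clinical")
#' contour set for this anatomy. Deterministic given the specification.
#'
#' @param spec A [phantomSpec()].
#' @return A [Phantom-class] with `fractionIndex = 0`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  gd <- spec$gridShape; sp <- spec$spacingMM
  masks <- list(); roles <- character(); densities <- numeric()
  for (g in spec$organGeometry) {
    m <- rasterizeShape(g, gd, sp)
    if (!is.null(g$union)) {
      for (nm in g$union) m <- m | masks[[nm]]
    }
    if (!is.null(g$subtract)) {
      for (nm in g$subtract) m <- m & !masks[[nm]]
    }
    masks[[g$name]] <- m
    roles[g$name] <- g$role
    densities[g$name] <- if (is.null(g$density)) spec$densityBackground else g$density
  }
  for (nm in names(masks)[roles == "target"]) {
    if (!any(masks[[nm]])) {
      stop("target structure '", nm, "' is empty after shape combination")
    }
  }
  if (!"external" %in% names(masks)) stop("template must define an external contour")
  density <- array(AIR_DENSITY, dim = gd)
  density[masks[["external"]]] <- spec$densityBackground
  for (nm in names(masks)) {
    if (nm != "external" && densities[nm] != spec$densityBackground) {
      density[masks[[nm]]] <- densities[nm]
    }
  }
  ss <- structureSet(masks, roles, templatePriorityMode(spec$template), sp)
  new("Phantom", density = density, structures = ss, spacing = sp,
      fractionIndex = 0L, template = spec$template)
}

#' Inter-fraction anatomical change model
#'
#' Describes the day-to-day anatomy deformation applied to a planning
#' phantom: a rigid shift (fixed component plus a random component drawn per
#' fraction), a smooth random organ-displacement field, an optional local
#' target volume rescaling, and an optional global shrinkage of the external
#' contour emulating weight loss in head-and-neck courses. Density and all
#' masks are deformed with the same field, so image and structures stay
#' consistent by construction.
#'
#' @param rigidShiftSdMM SD of the random rigid shift per axis (mm, `>= 0`).
#' @param rigidShiftMM Fixed rigid shift (mm, 3-vector).
#' @param organDisplacementAmpMM Per-component SD of the smooth random
#'   displacement field (mm, `>= 0`).
#' @param targetVolumeScale Multiplicative target volume change (1 = none).
#' @param externalShrinkFraction Fractional external volume loss in `[0, 0.3]`.
#' @param correlationLengthMM Smoothness scale of the random field (mm).
#' @param seed Integer seed; the per-fraction stream is derived from it.
#' @return A validated list of class `"AnatomyChangeModel"`.
#' @export
anatomyChangeModel <- function(rigidShiftSdMM = 2,
                               rigidShiftMM = c(0, 0, 0),
                               organDisplacementAmpMM = 6,
                               targetVolumeScale = 1,
                               externalShrinkFraction = 0,
                               correlationLengthMM = 40,
                               seed = 1L) {
  stopifnot(rigidShiftSdMM >= 0, organDisplacementAmpMM >= 0,
            targetVolumeScale > 0, correlationLengthMM > 0)
  if (externalShrinkFraction < 0 || externalShrinkFraction > 0.3) {
    stop("externalShrinkFraction must lie in [0, 0.3]")
  }
  structure(list(
    rigidShiftSdMM = rigidShiftSdMM,
    rigidShiftMM = as.numeric(rep_len(rigidShiftMM, 3L)),
    organDisplacementAmpMM = organDisplacementAmpMM,
    targetVolumeScale = targetVolumeScale,
    externalShrinkFraction = externalShrinkFraction,
    correlationLengthMM = correlationLengthMM,
    seed = as.integer(seed)
  ), class = "AnatomyChangeModel")
}

touchesBoundary <- function(mask) {
  d <- dim(mask)
  any(mask[1, , ]) || any(mask[d[1], , ]) || any(mask[, 1, ]) ||
    any(mask[, d[2], ]) || any(mask[, , 1]) || any(mask[, , d[3]])
}

# Displacement field realisation for one fraction (mm).
fractionField <- function(planning, model, fractionIndex) {
  gd <- gridShape(planning); sp <- voxelSpacing(planning)
  fseed <- model$seed + 7919L * as.integer(fractionIndex)
  shift <- model$rigidShiftMM +
    withSeed(fseed, stats::rnorm(3, sd = model$rigidShiftSdMM))
  rand <- smoothRandomField(gd, sp, model$organDisplacementAmpMM,
                            model$correlationLengthMM, seed = fseed + 1L)
  vec <- rand@vectors
  for (ax in 1:3) vec[, , , ax] <- vec[, , , ax] + shift[ax]
  cc <- axisCoords(gd, sp)
  if (model$externalShrinkFraction > 0) {
    cfac <- (1 - model$externalShrinkFraction)^(1 / 3)
    center <- gd * sp / 2
    for (ax in 1:3) {
      rel <- switch(ax,
        outerSum3(cc[[1]] - center[1], rep(0, gd[2]), rep(0, gd[3])),
        outerSum3(rep(0, gd[1]), cc[[2]] - center[2], rep(0, gd[3])),
        outerSum3(rep(0, gd[1]), rep(0, gd[2]), cc[[3]] - center[3]))
      vec[, , , ax] <- vec[, , , ax] + (1 - 1 / cfac) * rel
    }
  }
  if (model$targetVolumeScale != 1) {
    ctfac <- model$targetVolumeScale^(1 / 3)
    tn <- names(structureRoles(planning@structures))[
      structureRoles(planning@structures) == "target"][1]
    tc <- maskCentroid(getMask(planning@structures, tn), sp)
    idx <- which(getMask(planning@structures, tn), arr.ind = TRUE)
    tr <- max(sqrt(rowSums((sweep(idx, 2, 0.5) %*% diag(sp) -
                              matrix(tc, nrow(idx), 3, byrow = TRUE))^2)))
    sigT <- 1.5 * tr
    r2 <- outerSum3((cc[[1]] - tc[1])^2, (cc[[2]] - tc[2])^2, (cc[[3]] - tc[3])^2)
    wloc <- exp(-r2 / (2 * sigT^2))
    for (ax in 1:3) {
      rel <- switch(ax,
        outerSum3(cc[[1]] - tc[1], rep(0, gd[2]), rep(0, gd[3])),
        outerSum3(rep(0, gd[1]), cc[[2]] - tc[2], rep(0, gd[3])),
        outerSum3(rep(0, gd[1]), rep(0, gd[2]), cc[[3]] - tc[3]))
      vec[, , , ax] <- vec[, , , ax] + (1 - 1 / ctfac) * rel * wloc
    }
  }
  displacementField(vec, sp)
}

#' Generate the anatomy of one treatment fraction
#'
#' Applies one realisation of the anatomical change model to the planning
#' phantom. The same displacement field deforms the density grid and every
#' clinical structure, and the warped structures are the ground truth for
#' that fraction. With all change amplitudes zero the daily phantom equals
#' the planning phantom.
#'
#' @param planning The planning [Phantom-class] (`fractionIndex` 0).
#' @param model An [anatomyChangeModel()].
#' @param fractionIndex Fraction number (`>= 1`).
#' @return A daily [Phantom-class].
#' @export
generateFraction <- function(planning, model, fractionIndex) {
  stopifnot(is(planning, "Phantom"), inherits(model, "AnatomyChangeModel"))
  fractionIndex <- as.integer(fractionIndex)
  if (fractionIndex < 1L) stop("fractionIndex must be >= 1")
  noChange <- model$rigidShiftSdMM == 0 && all(model$rigidShiftMM == 0) &&
    model$organDisplacementAmpMM == 0 && model$targetVolumeScale == 1 &&
    model$externalShrinkFraction == 0
  if (noChange) {
    out <- planning
    out@fractionIndex <- fractionIndex
    return(out)
  }
  field <- fractionField(planning, model, fractionIndex)
  density <- warpScalar(planning@density, field, outside = AIR_DENSITY)
  density[density < 0] <- 0
  ss <- planning@structures
  masks <- lapply(ss@masks, warpMask, field = field)
  for (nm in names(masks)[structureRoles(ss) == "target"]) {
    if (!any(masks[[nm]]) || touchesBoundary(masks[[nm]])) {
      stop("deformation pushed target '", nm, "' outside the grid at fraction ",
           fractionIndex)
    }
  }
  newSS <- structureSet(masks, ss@roles, ss@priorityMode, ss@spacing)
  new("Phantom", density = density, structures = newSS,
      spacing = planning@spacing, fractionIndex = fractionIndex,
      template = planning@template)
}
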