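# Analytic proton dose engine: WED, Bragg curve, spot placement, scenarios,
# influence matrices.

test_that("WED grows linearly with depth in uniform media", {
  ph1 <- uniformPhantom(20, spacingMM = 4, density = 1)
  prof <- waterEquivalentDepth(ph1, entryMM = c(0, 40, 40), direction = c(1, 0, 0),
                               stepMM = 1)
  inside <- prof$distanceMM > 2 & prof$distanceMM < 78
  expect_lt(max(abs(prof$wedMM[inside] - prof$distanceMM[inside])), 1.0)

  ph05 <- uniformPhantom(20, spacingMM = 4, density = 0.5)
  prof <- waterEquivalentDepth(ph05, entryMM = c(0, 40, 40), direction = c(1, 0, 0),
                               stepMM = 1)
  w40 <- prof$wedMM[which.min(abs(prof$distanceMM - 40))]
  expect_lt(abs(w40 - 20), 1.0)
})

test_that("WED matches a piecewise product oracle on a slab phantom", {
  ph <- uniformPhantom(20, spacingMM = 4, density = 1)
  dens <- densityGrid(ph)
  dens[1:5, , ] <- 0.3    # 20 mm slab at 0.3
  dens[6:10, , ] <- 1.2   # 20 mm slab at 1.2
  ph@density <- dens
  prof <- waterEquivalentDepth(ph, entryMM = c(0, 40, 40), direction = c(1, 0, 0),
                               stepMM = 0.5)
  # after 40 mm: 20*0.3 + 20*1.2 = 30 mm WED
  w40 <- prof$wedMM[which.min(abs(prof$distanceMM - 40))]
  expect_lt(abs(w40 - 30), 1.0)
  expect_true(all(diff(prof$wedMM) >= 0))
  expect_error(
    waterEquivalentDepth(ph, entryMM = c(-500, -500, -500), direction = c(0, 0, -1)),
    "does not intersect")
})

test_that("the Bragg curve honours its shape contract", {
  for (R in c(60, 120, 250)) {
    wed <- seq(0.01, 1.4 * R, length.out = 4000)
    b <- braggCurve(wed, R)
    peak <- max(b)
    expect_lt(abs(wed[which.max(b)] - R) / R, 0.02)      # peak at the range
    entrance <- braggCurve(0.01 * R, R) / peak
    expect_gt(entrance, 0.2); expect_lt(entrance, 0.6)   # entrance plateau
    expect_lt(max(braggCurve(wed[wed >= 1.05 * R], R)) / peak, 0.01)  # distal falloff
    expect_true(all(is.finite(b)))
  }
})

test_that("the scenario set enumerates the robustness model", {
  sc <- scenarioSet()
  expect_length(sc, 9L)
  expect_identical(sc[[1]]$label, "nominal")
  shifts <- t(vapply(sc, function(s) s$setupShiftMM, numeric(3)))
  norms <- sqrt(rowSums(shifts^2))
  expect_equal(sort(unique(round(norms, 9))), c(0, 3))
  expect_equal(sum(norms > 0), 6)
  scales <- vapply(sc, function(s) s$rangeScale, numeric(1))
  expect_setequal(round(unique(scales), 6), c(1, 0.97, 1.03))
  expect_length(scenarioSet(0, 0), 1L)
  expect_length(scenarioSet(crossProduct = TRUE), 21L)
})

test_that("spot placement covers every target voxel and scales with beams and margin", {
  ph <- uniformPhantom(24, spacingMM = 4, targetRadiusMM = 20)
  beam <- beamConfig(c(1, 0, 0), lateralSpacingMM = 8, layerSpacingMM = 6,
                     targetMarginMM = 0)
  spots <- placeSpots(ph, list(beam))
  st <- spotTable(spots)
  target <- getMask(clinicalStructures(ph), "target")
  idx <- which(target, arr.ind = TRUE)
  pos <- sweep(idx - 0.5, 2, voxelSpacing(ph), `*`)
  fr <- adaptIMPT:::beamFrame(beam$direction)
  lu <- as.numeric(pos %*% fr$u); lv <- as.numeric(pos %*% fr$v)
  wed <- adaptIMPT:::wedGridForBeam(ph, beam$direction)[target]
  for (i in seq_along(lu)) {
    dmin <- min(pmax(abs(st$u - lu[i]), abs(st$v - lv[i])))
    expect_lte(dmin, beam$lateralSpacingMM)
    expect_lte(min(abs(st$range - wed[i])), beam$layerSpacingMM)
  }
  two <- placeSpots(ph, list(beam, beam))
  expect_equal(nSpots(two), 2L * nSpots(spots))
  wide <- placeSpots(ph, list(beamConfig(c(1, 0, 0), lateralSpacingMM = 8,
                                         layerSpacingMM = 6, targetMarginMM = 5)))
  expect_gte(nSpots(wide), nSpots(spots))
  empty <- ph
  expect_error(placeSpots(ph, list(beam), targetNames = character(0)), "mask")
})

singleSpotGrid <- function(u, v, range, direction = c(1, 0, 0), sigma = 6) {
  new("SpotGrid",
      spots = data.frame(beam = 1L, u = u, v = v, range = range),
      beams = list(beamConfig(direction, lateralSigmaMM = sigma)))
}

test_that("a single spot deposits its maximum at the Bragg position", {
  ph <- uniformPhantom(24, spacingMM = 4, density = 1)
  fr <- adaptIMPT:::beamFrame(c(1, 0, 0))
  ctr <- c(48, 48)  # mid (y, z) in mm
  spot <- singleSpotGrid(u = sum(c(0, ctr[1], ctr[2]) * fr$u),
                         v = sum(c(0, ctr[1], ctr[2]) * fr$v), range = 50)
  infl <- buildInfluence(ph, spot, floorFrac = 1e-4)
  dose <- computeDose(infl, 1)
  mx <- which(dose == max(dose), arr.ind = TRUE)[1, ]
  pos <- (mx - 0.5) * voxelSpacing(ph)
  expect_lte(abs(pos[1] - 50), 4)   # depth at range (unit density)
  expect_lte(abs(pos[2] - 48), 4)
  expect_lte(abs(pos[3] - 48), 4)
})

test_that("the nominal scenario equals building with no scenario argument", {
  ph <- uniformPhantom(20, spacingMM = 4)
  spots <- placeSpots(ph, list(beamConfig(c(1, 0, 0))))
  a <- buildInfluence(ph, spots)
  b <- buildInfluence(ph, spots, scenario = list(setupShiftMM = c(0, 0, 0),
                                                 rangeScale = 1, label = "nominal"))
  expect_identical(a@dose, b@dose)
})

test_that("a setup shift acts as a rigid dose shift on a uniform phantom", {
  ph <- uniformPhantom(24, spacingMM = 4)
  fr <- adaptIMPT:::beamFrame(c(1, 0, 0))
  spot <- singleSpotGrid(u = sum(c(0, 48, 48) * fr$u),
                         v = sum(c(0, 48, 48) * fr$v), range = 50)
  nom <- computeDose(buildInfluence(ph, spot), 1)
  sc <- list(setupShiftMM = c(4, 0, 0), rangeScale = 1, label = "x+4")
  shifted <- computeDose(buildInfluence(ph, spot, sc), 1)
  # dose under a +4 mm (one voxel) patient shift equals the nominal dose
  # shifted by -1 voxel along x (interior voxels)
  interior <- 3:22
  expect_lt(max(abs(shifted[interior, , ] - nom[interior + 1, , ])), 0.02)
})

test_that("range scaling moves the single-spot peak depth to range/scale", {
  ph <- uniformPhantom(32, spacingMM = 4)
  fr <- adaptIMPT:::beamFrame(c(1, 0, 0))
  spot <- singleSpotGrid(u = sum(c(0, 64, 64) * fr$u),
                         v = sum(c(0, 64, 64) * fr$v), range = 80)
  for (rs in c(0.9, 1.1)) {
    sc <- list(setupShiftMM = c(0, 0, 0), rangeScale = rs, label = "r")
    dose <- computeDose(buildInfluence(ph, spot, sc), 1)
    depth <- (which(dose == max(dose), arr.ind = TRUE)[1, 1] - 0.5) * 4
    expect_lte(abs(depth - 80 / rs), 6)
  }
})

test_that("compute dose is exactly linear and matches a dense oracle", {
  set.seed(11)
  n <- 10
  A <- matrix(stats::runif(10 * n^3) * (stats::runif(10 * n^3) < 0.1), nrow = 10)
  infl <- new("InfluenceMatrix", dose = sparseGeneral(A),
              scenario = list(label = "nominal"), gridDim = rep(as.integer(n), 3),
              spacing = c(4, 4, 4))
  w <- stats::runif(10)
  expect_equal(as.numeric(computeDose(infl, w, 2)), as.numeric(2 * t(A) %*% w))
  expect_true(all(computeDose(infl, rep(0, 10)) == 0))
  expect_equal(computeDose(infl, 2 * w), 2 * computeDose(infl, w))
  expect_error(computeDose(infl, -w), ">= 0")
  expect_error(computeDose(infl, w[1:3]), "spot count")
})
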