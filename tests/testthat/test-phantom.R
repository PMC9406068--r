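# Synthetic phantom generation and per-fraction anatomical change.

test_that("phantom generation is deterministic and matches the template roster", {
  spec <- phantomSpec("abdomen", gridShape = c(24, 24, 24), seed = 11,
                      jitterSdMM = 3, radiusJitterFrac = 0.06)
  p1 <- generatePhantom(spec)
  p2 <- generatePhantom(spec)
  expect_identical(densityGrid(p1), densityGrid(p2))
  expect_identical(clinicalStructures(p1)@masks, clinicalStructures(p2)@masks)

  roles <- structureRoles(clinicalStructures(p1))
  expect_setequal(names(roles)[roles != "external"],
                  c("ctv", "stomach", "small_bowel", "large_bowel", "duodenum",
                    "spinal_cord", "kidneys", "liver"))
  expect_identical(unname(roles[["ctv"]]), "target")
  expect_identical(priorityMode(clinicalStructures(p1)), "stereotactic")
})

test_that("the abdominal CTV volume lies in the clinically reported band", {
  for (seed in 1:3) {
    ph <- generatePhantom(phantomSpec("abdomen", gridShape = c(32, 32, 32),
                                     seed = seed, jitterSdMM = 3,
                                     radiusJitterFrac = 0.06))
    v <- volumeCC(getMask(clinicalStructures(ph), "ctv"), voxelSpacing(ph))
    expect_gt(v, 15)
    expect_lt(v, 125)
  }
})

test_that("the head and neck template nests the CTVs and has the clinical roster", {
  ph <- generatePhantom(phantomSpec("head_neck", gridShape = c(28, 28, 28)))
  ss <- clinicalStructures(ph)
  roles <- structureRoles(ss)
  expect_setequal(names(roles)[roles != "external"],
                  c("ctv_high", "ctv_low", "brainstem", "spinal_cord",
                    "constrictors", "larynx", "parotids"))
  high <- getMask(ss, "ctv_high"); low <- getMask(ss, "ctv_low")
  expect_true(all(low[high]))  # low-risk CTV contains the high-risk CTV
  expect_identical(priorityMode(ss), "coverage")
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantomSpec("lung"), "arg")
  expect_error(phantomSpec("abdomen", gridShape = c(8, 24, 24)), ">= 16")
  expect_error(phantomSpec("abdomen", gridShape = c(24, 24, 24), spacingMM = -1),
               "positive")
  # geometry pushed outside the grid
  geom <- defaultGeom <- adaptIMPT:::defaultOrganGeometry("abdomen")
  geom[[2]]$center <- c(500, 120, 120)
  expect_error(phantomSpec("abdomen", organGeometry = geom), "inside the grid")
})

test_that("a zero-amplitude change model reproduces the planning phantom", {
  planning <- generatePhantom(phantomSpec("abdomen", gridShape = c(24, 24, 24)))
  model <- anatomyChangeModel(rigidShiftSdMM = 0, organDisplacementAmpMM = 0)
  daily <- generateFraction(planning, model, 1)
  expect_identical(densityGrid(daily), densityGrid(planning))
  expect_identical(clinicalStructures(daily)@masks, clinicalStructures(planning)@masks)
  expect_identical(daily@fractionIndex, 1L)
})

test_that("a pure rigid shift moves every mask centroid by the shift", {
  planning <- generatePhantom(phantomSpec("abdomen", gridShape = c(24, 24, 24)))
  sp <- voxelSpacing(planning)
  model <- anatomyChangeModel(rigidShiftSdMM = 0, organDisplacementAmpMM = 0,
                              rigidShiftMM = c(2 * sp[1], 0, 0))
  daily <- generateFraction(planning, model, 1)
  for (nm in c("ctv", "liver", "stomach")) {
    c0 <- adaptIMPT:::maskCentroid(getMask(clinicalStructures(planning), nm), sp)
    c1 <- adaptIMPT:::maskCentroid(getMask(clinicalStructures(daily), nm), sp)
    expect_lt(abs((c1 - c0)[1] - 2 * sp[1]), 0.5 * sp[1])
    expect_lt(abs((c1 - c0)[2]), 0.5 * sp[2])
    expect_lt(abs((c1 - c0)[3]), 0.5 * sp[3])
  }
})

test_that("external shrinkage reduces the external volume by the set fraction", {
  planning <- generatePhantom(phantomSpec("head_neck", gridShape = c(32, 32, 32)))
  model <- anatomyChangeModel(rigidShiftSdMM = 0, organDisplacementAmpMM = 0,
                              externalShrinkFraction = 0.1)
  daily <- generateFraction(planning, model, 1)
  v0 <- volumeCC(getMask(clinicalStructures(planning), "external"),
                 voxelSpacing(planning))
  v1 <- volumeCC(getMask(clinicalStructures(daily), "external"),
                 voxelSpacing(daily))
  expect_lt(abs(v1 / v0 - 0.9), 0.02)
})

test_that("deformations that push the target off the grid raise an error", {
  planning <- generatePhantom(phantomSpec("abdomen", gridShape = c(24, 24, 24)))
  model <- anatomyChangeModel(rigidShiftSdMM = 0, organDisplacementAmpMM = 0,
                              rigidShiftMM = c(200, 0, 0))
  expect_error(generateFraction(planning, model, 1), "outside the grid")
  expect_error(generateFraction(planning, model, 0), ">= 1")
})
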