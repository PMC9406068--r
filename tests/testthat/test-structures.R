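# Contour-ensemble algebra and volumes.

bruteOr <- function(masks) {
  out <- array(FALSE, dim = dim(masks[[1]]))
  for (i in seq_along(out)) out[i] <- any(vapply(masks, function(m) m[i], logical(1)))
  out
}
bruteAnd <- function(masks) {
  out <- array(FALSE, dim = dim(masks[[1]]))
  for (i in seq_along(out)) out[i] <- all(vapply(masks, function(m) m[i], logical(1)))
  out
}

test_that("union and intersection match the per-voxel oracle and obey set algebra", {
  m <- sphereMask(12, 4)
  expect_identical(maskUnion(list(m, m)), m)          # idempotence
  expect_identical(maskIntersection(list(m, m)), m)
  a <- array(FALSE, dim = c(10, 10, 10)); a[1:5, 1, 1] <- TRUE
  b <- array(FALSE, dim = c(10, 10, 10)); b[6:10, 2, 2] <- TRUE
  expect_equal(sum(maskUnion(list(a, b))), sum(a) + sum(b))   # disjoint additivity
  expect_equal(sum(maskIntersection(list(a, b))), 0)
  set.seed(1)
  for (rep in 1:5) {
    masks <- lapply(1:3, function(i) randomMask(8, 0.4))
    expect_identical(maskUnion(masks), bruteOr(masks))
    expect_identical(maskIntersection(masks), bruteAnd(masks))
    u <- maskUnion(masks); it <- maskIntersection(masks)
    for (m in masks) {
      expect_true(all(m[it]))   # intersection within each input
      expect_true(all(u[m]))    # each input within union
    }
  }
  bad <- list(randomMask(8), randomMask(10))
  expect_error(maskUnion(bad), "grid")
})

test_that("agreement values are the ensemble classification frequencies", {
  n <- 8
  base <- array(FALSE, dim = rep(n, 3))
  m1 <- base; m1[1:4, 1, 1] <- TRUE          # voxels 1-4
  m2 <- base; m2[2:4, 1, 1] <- TRUE          # voxels 2-4
  m3 <- base; m3[3:4, 1, 1] <- TRUE          # voxels 3-4
  mkSet <- function(m) structureSet(list(t = m), c(t = "target"), "coverage", c(1, 1, 1))
  am <- agreementMap(list(mkSet(m1), mkSet(m2), mkSet(m3)))
  v <- am@values$t
  expect_equal(v[1, 1, 1], 1 / 3)
  expect_equal(v[2, 1, 1], 2 / 3)
  expect_equal(v[3, 1, 1], 1)
  expect_equal(v[5, 1, 1], 0)
  # 1 exactly on the intersection, > 0 exactly on the union
  expect_identical(array(v == 1, dim = dim(v)), maskIntersection(list(m1, m2, m3)))
  expect_identical(array(v > 0, dim = dim(v)), maskUnion(list(m1, m2, m3)))
})

test_that("agreement map rejects mismatched rosters", {
  s1 <- structureSet(list(a = randomMask(8)), c(a = "target"), "coverage", c(1, 1, 1))
  s2 <- structureSet(list(b = randomMask(8)), c(b = "target"), "coverage", c(1, 1, 1))
  expect_error(agreementMap(list(s1, s2)), "rosters differ")
})

test_that("substructure levels are an exact-level partition of the ensemble union", {
  set.seed(2)
  ens <- randomEnsemble(n = 12, K = 3)
  am <- agreementMap(ens)
  subs <- substructurePartition(am, 3)
  expect_setequal(names(subs@levels$t), c("33", "67", "100"))
  for (nm in c("t", "o")) {
    lv <- subs@levels[[nm]]
    counts <- round(am@values[[nm]] * 3)
    expect_identical(lv[["67"]], array(counts == 2, dim = dim(counts)))
    expect_identical(lv[["33"]], array(counts == 1, dim = dim(counts)))
    # pairwise disjoint and covering the union
    total <- lv[["33"]] + lv[["67"]] + lv[["100"]]
    expect_true(all(total <= 1))
    u <- maskUnion(lapply(ens, getMask, name = nm))
    expect_identical(array(total == 1, dim = dim(total)), u)
  }
  expect_error(substructurePartition(am, 4), "ensemble size")
})

test_that("conservative combination follows the prescription priority", {
  set.seed(3)
  ens <- randomEnsemble(n = 10, K = 3)
  stereo <- conservativeCombination(ens, "stereotactic")
  expect_identical(getMask(stereo, "t"),
                   maskIntersection(lapply(ens, getMask, name = "t")))
  expect_identical(getMask(stereo, "o"),
                   maskUnion(lapply(ens, getMask, name = "o")))
  cov <- conservativeCombination(ens, "coverage")
  expect_identical(getMask(cov, "t"), maskUnion(lapply(ens, getMask, name = "t")))
  same <- conservativeCombination(list(ens[[1]], ens[[1]], ens[[1]]), "stereotactic")
  expect_identical(same@masks, ens[[1]]@masks)
})

test_that("an empty conservative target intersection warns and is flagged", {
  base <- array(FALSE, dim = c(8, 8, 8))
  m1 <- base; m1[1:2, 1, 1] <- TRUE
  m2 <- base; m2[5:6, 1, 1] <- TRUE
  mkSet <- function(m) structureSet(list(t = m, o = m), c(t = "target", o = "oar"),
                                    "stereotactic", c(1, 1, 1))
  expect_warning(out <- conservativeCombination(list(mkSet(m1), mkSet(m2))),
                 "empty target")
  expect_identical(attr(out, "emptyTarget"), "t")
})

test_that("volumes are voxel count times voxel volume", {
  m <- array(FALSE, dim = c(20, 20, 20)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(volumeCC(m, c(2, 2, 2)), 8)
  expect_equal(volumeCC(array(FALSE, dim = c(4, 4, 4)), c(1, 1, 1)), 0)
  set.seed(4)
  for (rep in 1:5) {
    mm <- randomMask(10, 0.5)
    cnt <- 0; for (i in seq_along(mm)) if (mm[i]) cnt <- cnt + 1
    expect_equal(volumeCC(mm, c(1.5, 2, 2.5)), cnt * 1.5 * 2 * 2.5 / 1000)
  }
})
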