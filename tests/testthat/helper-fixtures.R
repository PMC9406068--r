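# Shared fixtures built in code: small phantoms, masks and toy problems.

# A uniform-density phantom with a single spherical target, for dose-engine
# tests where analytic expectations need a homogeneous medium.
uniformPhantom <- function(n = 24, spacingMM = 4, density = 1,
                           targetRadiusMM = 20) {
  gd <- rep(n, 3L)
  sp <- rep(spacingMM, 3L)
  dens <- array(density, dim = gd)
  cc <- lapply(1:3, function(ax) (seq_len(n) - 0.5) * spacingMM)
  ctr <- n * spacingMM / 2
  r2 <- outer(outer((cc[[1]] - ctr)^2, (cc[[2]] - ctr)^2, `+`), (cc[[3]] - ctr)^2, `+`)
  target <- r2 <= targetRadiusMM^2
  ss <- structureSet(list(target = target),
                     c(target = "target"), "coverage", sp)
  new("Phantom", density = dens, structures = ss, spacing = sp,
      fractionIndex = 0L, template = "abdomen")
}

sphereMask <- function(n, radiusVox, center = rep((n + 1) / 2, 3)) {
  cc <- seq_len(n)
  r2 <- outer(outer((cc - center[1])^2, (cc - center[2])^2, `+`),
              (cc - center[3])^2, `+`)
  array(r2 <= radiusVox^2, dim = rep(n, 3))
}

randomMask <- function(n, p = 0.3) {
  array(stats::runif(n^3) < p, dim = rep(n, 3))
}

# Tiny structure set ensemble on a shared grid for ensemble-algebra tests.
randomEnsemble <- function(n = 16, K = 3, p = 0.3, spacing = c(2, 2, 2)) {
  lapply(seq_len(K), function(k) {
    masks <- list(t = randomMask(n, p), o = randomMask(n, p))
    structureSet(masks, c(t = "target", o = "oar"), "coverage", spacing)
  })
}

# dgCMatrix regardless of symmetry pattern detection
sparseGeneral <- function(m) {
  as(as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
     "dMatrix")
}

# A 2-spot, 2-voxel toy minimax problem with a known brute-force optimum.
toyProblem <- function(scenarioMats, targetLevel = 10, oarLevel = 3,
                       oarWeight = 10, nFractions = 1) {
  influences <- lapply(seq_along(scenarioMats), function(i) {
    new("InfluenceMatrix",
        dose = sparseGeneral(scenarioMats[[i]]),
        scenario = list(setupShiftMM = c(0, 0, 0), rangeScale = 1,
                        label = paste0("s", i)),
        gridDim = c(2L, 1L, 1L), spacing = c(10, 10, 10))
  })
  terms <- list(
    adaptIMPT:::resolveTerm(objectiveTerm("t", "min_dose", targetLevel), 1L),
    adaptIMPT:::resolveTerm(objectiveTerm("o", "max_dose", oarLevel,
                                          weight = oarWeight), 2L)
  )
  spots <- new("SpotGrid",
               spots = data.frame(beam = c(1L, 1L), u = c(0, 10), v = c(0, 0),
                                  range = c(50, 50)),
               beams = list(beamConfig(c(1, 0, 0))))
  robustProblem(list(terms), influences, spots = spots,
                nFractions = nFractions, spacing = c(10, 10, 10))
}

toyObjective <- function(w, scenarioMats, targetLevel = 10, oarLevel = 3,
                         oarWeight = 10) {
  max(vapply(scenarioMats, function(A) {
    d <- as.numeric(t(A) %*% w)
    max(0, targetLevel - d[1])^2 + oarWeight * max(0, d[2] - oarLevel)^2
  }, numeric(1)))
}
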