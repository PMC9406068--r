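# Strategy problem construction and the planning invariants.

# Small shared setup: a daily phantom with simulated DIR sets and scenario
# influences on a coarse grid.
strategyFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    planning <- generatePhantom(phantomSpec("abdomen", gridShape = c(24, 24, 24)))
    beams <- templateBeams("abdomen")
    spots <- placeSpots(planning, beams)
    scen <- scenarioSet()
    infl <- lapply(scen, function(s) buildInfluence(planning, spots, s))
    cons <- templateConstraints("abdomen")
    tps <- adaptIMPT:::templatePlanSpec("abdomen")
    # coarse fixture grid: allow identical draws (band upper bound 1)
    noise <- dirNoiseModel(targetDiceBand = c(0.5, 1), seed = 5)
    dirSets <- simulateDirSets(planning, noise)
    cache <<- list(planning = planning, spots = spots, infl = infl,
                   cons = cons, tps = tps, dirSets = dirSets)
    cache
  }
})

termSignature <- function(terms) {
  sig <- vapply(terms, function(tm) {
    paste(tm$structure, tm$kind, tm$doseGy, sep = "|")
  }, character(1))
  sort(unique(sig))
}

test_that("every optimizing strategy is built from the same constraint list", {
  fx <- strategyFixture()
  tags <- c("single_dir_1", "single_dir_2", "multi_dir", "conservative",
            "probabilistic", "reference")
  sigs <- lapply(tags, function(tag) {
    built <- buildStrategyProblem(tag, fx$planning, fx$dirSets,
                                  clinicalSet = clinicalStructures(fx$planning),
                                  constraints = fx$cons, influences = fx$infl,
                                  spots = fx$spots, nFractions = 5,
                                  extraTerms = fx$tps$extraTerms)
    expect_identical(built$type, "optimize")
    termSignature(unlist(built$problem$objectives, recursive = FALSE))
  })
  for (s in sigs[-1]) expect_identical(s, sigs[[1]])
})

test_that("probabilistic term weights carry the exact k/K agreement factors", {
  fx <- strategyFixture()
  built <- buildStrategyProblem("probabilistic", fx$planning, fx$dirSets,
                                clinicalSet = clinicalStructures(fx$planning),
                                constraints = fx$cons, influences = fx$infl,
                                spots = fx$spots, nFractions = 5,
                                extraTerms = fx$tps$extraTerms)
  terms <- built$problem$objectives[[1]]
  # the coverage constraint on the target is soft (base weight 1)
  covTerms <- Filter(function(tm) tm$structure == "ctv" && tm$kind == "min_dose",
                     terms)
  w <- sort(unique(vapply(covTerms, `[[`, numeric(1), "weight")))
  expect_true(all(w %in% c(1 / 3, 2 / 3, 1)))
  expect_gte(length(w), 2)

  am <- agreementMap(fx$dirSets)
  subs <- substructurePartition(am, 3)
  lvl67 <- which(subs@levels$ctv[["67"]])
  tm67 <- Filter(function(tm) tm$structure == "ctv" && tm$kind == "min_dose" &&
                   abs(tm$weight - 2 / 3) < 1e-12, terms)
  if (length(tm67)) expect_identical(tm67[[1]]$maskIdx, lvl67)
})

test_that("multi-DIR with identical sets reduces to the single-DIR problem", {
  fx <- strategyFixture()
  same <- list(clinicalStructures(fx$planning), clinicalStructures(fx$planning),
               clinicalStructures(fx$planning))
  multi <- buildStrategyProblem("multi_dir", fx$planning, same,
                                clinicalSet = clinicalStructures(fx$planning),
                                constraints = fx$cons, influences = fx$infl,
                                spots = fx$spots, nFractions = 5,
                                extraTerms = fx$tps$extraTerms)
  single <- buildStrategyProblem("reference", fx$planning, same,
                                 clinicalSet = clinicalStructures(fx$planning),
                                 constraints = fx$cons, influences = fx$infl,
                                 spots = fx$spots, nFractions = 5,
                                 extraTerms = fx$tps$extraTerms)
  expect_length(multi$problem$objectives, 1L)
  expect_identical(multi$problem$objectives, single$problem$objectives)
  expect_identical(nrow(multi$problem$pairs), nrow(single$problem$pairs))
})

test_that("no adaptation returns the initial weights unchanged", {
  fx <- strategyFixture()
  w0 <- stats::runif(nSpots(fx$spots))
  initial <- new("Plan", weights = w0, spots = fx$spots, strategy = "initial",
                 diagnostics = list())
  built <- buildStrategyProblem("no_adaptation", fx$planning, fx$dirSets,
                                clinicalSet = clinicalStructures(fx$planning),
                                constraints = fx$cons, influences = fx$infl,
                                initialPlan = initial, spots = fx$spots,
                                nFractions = 5)
  expect_identical(built$type, "fixed")
  expect_identical(planWeights(built$plan), w0)
  expect_identical(strategyTag(built$plan), "no_adaptation")
})

test_that("unknown strategy tags and missing DIR sets are rejected", {
  fx <- strategyFixture()
  expect_error(buildStrategyProblem("mystery", fx$planning, fx$dirSets,
                                    clinicalSet = clinicalStructures(fx$planning),
                                    constraints = fx$cons, influences = fx$infl,
                                    spots = fx$spots), "unknown strategy")
  expect_error(buildStrategyProblem("single_dir_9", fx$planning, fx$dirSets,
                                    clinicalSet = clinicalStructures(fx$planning),
                                    constraints = fx$cons, influences = fx$infl,
                                    spots = fx$spots), "missing DIR set")
})

test_that("the initial plan covers an easy, well-separated target", {
  # custom geometry: target in the middle, organs far away
  geom <- list(
    list(name = "external", role = "external", type = "ellipsoid",
         center = c(120, 120, 120), radii = c(105, 100, 105), density = 1),
    list(name = "ctv", role = "target", type = "ellipsoid",
         center = c(120, 120, 120), radii = c(25, 25, 24), density = 1.02),
    list(name = "stomach", role = "oar", type = "ellipsoid",
         center = c(40, 190, 180), radii = c(15, 15, 15), density = 1),
    list(name = "spinal_cord", role = "oar", type = "cylinderZ",
         center = c(120, 30), radius = 7, zRange = c(40, 200), density = 1.04)
  )
  spec <- phantomSpec("abdomen", gridShape = c(30, 30, 30), organGeometry = geom)
  ph <- generatePhantom(spec)
  cons <- constraintTable(
    c("ctv", "stomach", "spinal_cord"),
    c("V47.5Gy > 95%", "V33Gy < 1 cc", "V25Gy < 0.5 cc"),
    c("soft", "hard", "hard"))
  spots <- placeSpots(ph, templateBeams("abdomen"))
  scen <- scenarioSet()
  infl <- lapply(scen, function(s) buildInfluence(ph, spots, s))
  plan <- optimizeInitialPlan(ph, cons, infl, spots, nFractions = 5,
                              config = solverConfig(maxit = 250))
  dose <- computeDose(infl[[1]], planWeights(plan), 5)
  ev <- evaluateConstraints(dose, clinicalStructures(ph), cons)
  expect_gte(ev$value[ev$structure == "ctv"], 95)   # coverage met
  expect_false(any(ev$violated))
  # deterministic given config
  plan2 <- optimizeInitialPlan(ph, cons, infl, spots, nFractions = 5,
                               config = solverConfig(maxit = 250))
  expect_identical(planWeights(plan), planWeights(plan2))
  # worst-case objective dominates every single-scenario objective
  pv <- plan@diagnostics$pairValues
  expect_gte(plan@diagnostics$objective + 1e-9, max(pv))
})

test_that("the multi-DIR plan dominates single-DIR plans under the shared worst case", {
  fx <- strategyFixture()
  build <- function(tag) {
    buildStrategyProblem(tag, fx$planning, fx$dirSets,
                         clinicalSet = clinicalStructures(fx$planning),
                         constraints = fx$cons, influences = fx$infl[1],
                         spots = fx$spots, nFractions = 5,
                         extraTerms = fx$tps$extraTerms)$problem
  }
  multiProb <- build("multi_dir")
  cfg <- solverConfig(maxit = 250)
  multiPlan <- solvePlan(multiProb, cfg)
  evalMulti <- function(w) {
    voxcc <- prod(voxelSpacing(fx$planning)) / 1000
    d <- as.numeric(Matrix::crossprod(fx$infl[[1]]@dose, w)) * 5
    max(vapply(multiProb$objectives, function(obj) {
      adaptIMPT:::compositeEval(obj, d, voxcc)$value
    }, numeric(1)))
  }
  fMulti <- evalMulti(planWeights(multiPlan))
  for (k in 1:3) {
    wk <- planWeights(solvePlan(build(paste0("single_dir_", k)), cfg))
    expect_lte(fMulti, evalMulti(wk) * 1.01 + 1e-9)
  }
})
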