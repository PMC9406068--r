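# Constraint evaluation, the violation-sum score, differencing, aggregation
# and the scoring-weight sensitivity scan.

# Minimal structure set + dose pair for targeted scoring checks.
scoreFixture <- function(doseIn = 50, doseOut = 0) {
  n <- 10
  m <- array(FALSE, dim = rep(n, 3)); m[3:7, 3:7, 3:7] <- TRUE
  o <- array(FALSE, dim = rep(n, 3)); o[9:10, 9:10, 9:10] <- TRUE
  ss <- structureSet(list(ctv = m, organ = o),
                     c(ctv = "target", organ = "oar"), "coverage", c(5, 5, 4))
  dose <- array(doseOut, dim = rep(n, 3)); dose[m] <- doseIn
  list(ss = ss, dose = dose)
}

test_that("values exactly at the limit are not violations", {
  fx <- scoreFixture(doseIn = 50)
  cons <- constraintTable(c("ctv", "organ"), c("V47.5Gy > 95%", "max < 54Gy"),
                          c("soft", "hard"))
  fx$dose[10, 10, 10] <- 54      # organ max exactly at the limit
  ev <- evaluateConstraints(fx$dose, fx$ss, cons)
  expect_equal(ev$value, c(100, 54))
  expect_false(any(ev$violated))
  expect_equal(scorePlan(ev)$total, 0)
})

test_that("violations contribute the absolute exceedance in native units", {
  fx <- scoreFixture()
  cons <- constraintTable(c("ctv", "organ", "organ"),
                          c("V47.5Gy > 95%", "max < 54Gy", "mean < 10Gy"),
                          c("soft", "hard", "hard"))
  fx$dose[9, 9, 9] <- 55         # organ max 55 vs 54 -> 1 au
  ev <- evaluateConstraints(fx$dose, fx$ss, cons)
  sc <- scorePlan(ev)
  expect_equal(sc$total, 1 + max(0, mean(fx$dose[getMask(fx$ss, "organ")]) - 10))
  expect_equal(ev$contribution[ev$text == "max < 54Gy"], 1)

  # percentage-point contributions for coverage shortfalls
  fx2 <- scoreFixture()
  ctv <- getMask(fx2$ss, "ctv")
  idx <- which(ctv)
  fx2$dose[idx[1:13]] <- 0       # 13 of 125 voxels cold -> 89.6% coverage
  ev2 <- evaluateConstraints(fx2$dose, fx2$ss,
                             constraintTable("ctv", "V66.5Gy > 95%", "hard"))
  expect_false(TRUE %in% (fx2$dose[idx] >= 66.5))
  ev3 <- evaluateConstraints(fx2$dose, fx2$ss,
                             constraintTable("ctv", "V47.5Gy > 95%", "hard"))
  expect_equal(ev3$value, 100 * 112 / 125)
  expect_equal(ev3$contribution, 95 - 100 * 112 / 125)
})

test_that("score reports compose: zero iff all met, monotone under worsening", {
  fx <- scoreFixture()
  cons <- constraintTable(c("ctv", "organ"), c("V47.5Gy > 95%", "max < 54Gy"),
                          c("soft", "hard"))
  ev <- evaluateConstraints(fx$dose, fx$ss, cons)
  expect_equal(scorePlan(ev)$total, 0)
  worse <- fx$dose; worse[9, 9, 9] <- 60
  evW <- evaluateConstraints(worse, fx$ss, cons)
  expect_gt(scorePlan(evW)$total, 0)
  worst <- fx$dose; worst[9, 9, 9] <- 70
  expect_gt(scorePlan(evaluateConstraints(worst, fx$ss, cons))$total,
            scorePlan(evW)$total)
})

test_that("missing structures are reported by name", {
  fx <- scoreFixture()
  cons <- constraintTable("duodenum", "V33Gy < 1 cc", "hard")
  expect_error(evaluateConstraints(fx$dose, fx$ss, cons), "duodenum")
})

test_that("score differencing is signed, antisymmetric and list-checked", {
  fx <- scoreFixture()
  cons <- constraintTable(c("ctv", "organ"), c("V47.5Gy > 95%", "max < 54Gy"),
                          c("soft", "hard"))
  a <- scorePlan(evaluateConstraints(fx$dose, fx$ss, cons))
  worse <- fx$dose; worse[9, 9, 9] <- 57
  b <- scorePlan(evaluateConstraints(worse, fx$ss, cons))
  expect_equal(scoreDifference(a, a), 0)
  expect_equal(scoreDifference(b, a), 3)
  expect_equal(scoreDifference(b, a), -scoreDifference(a, b))
  other <- scorePlan(evaluateConstraints(fx$dose, fx$ss,
                                         constraintTable("ctv", "V47.5Gy > 95%", "soft")))
  expect_error(scoreDifference(a, other), "different constraint lists")
})

test_that("aggregation reports mean, min and max per strategy and template", {
  res <- data.frame(template = "abdomen", phantom = 1, fraction = 1:3,
                    strategy = "single_dir_1", scoreDiff = c(1, 2, 3))
  agg <- aggregateScores(res)
  expect_equal(agg$mean, 2); expect_equal(agg$min, 1); expect_equal(agg$max, 3)
  one <- aggregateScores(res[1, ])
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  # direct recomputation from the raw table
  set.seed(31)
  big <- expand.grid(template = c("abdomen", "head_neck"), phantom = 1:2,
                     fraction = 1:2,
                     strategy = c("reference", "no_adaptation"))
  big$scoreDiff <- stats::rnorm(nrow(big))
  agg <- aggregateScores(big)
  for (i in seq_len(nrow(agg))) {
    sel <- big$template == agg$template[i] & big$strategy == agg$strategy[i]
    expect_equal(agg$mean[i], mean(big$scoreDiff[sel]))
    expect_equal(agg$max[i], max(big$scoreDiff[sel]))
  }
})

sensFixture <- function() {
  grid <- expand.grid(template = "abdomen", phantom = 1:2, fraction = 1:2,
                      strategy = c("reference", "single_dir_1", "no_adaptation"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    base <- switch(g$strategy, reference = 1, single_dir_1 = 3, no_adaptation = 8)
    data.frame(template = g$template, phantom = g$phantom, fraction = g$fraction,
               strategy = g$strategy, label = c("t", "o"),
               role = c("target", "oar"), value = NA, limit = NA,
               violated = TRUE, contribution = base * c(0.4, 0.6))
  }))
  rows
}

test_that("sensitivity: multiplier 1 reproduces the ranking and scaling is invariant", {
  contrib <- sensFixture()
  sens <- sensitivityAnalysis(contrib, multipliers = 1:10)
  base <- sens$table[sens$table$multiplier == 1 & sens$table$mode == "target", ]
  expect_identical(base$strategy[order(base$rank)],
                   c("reference", "single_dir_1", "no_adaptation"))
  expect_true(all(sens$stability$bestStable))
  expect_true(all(sens$stability$worstStable))
  # multiplying ALL contributions by a constant leaves every ranking unchanged
  scaled <- contrib; scaled$contribution <- scaled$contribution * 7
  sens2 <- sensitivityAnalysis(scaled, multipliers = 1:10)
  expect_identical(sens$table[, c("template", "mode", "multiplier", "strategy", "rank")],
                   sens2$table[, c("template", "mode", "multiplier", "strategy", "rank")])
})
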