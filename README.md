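# adaptIMPT

Desk-scale simulation of strategies for handling **contour-propagation
uncertainty in online adaptive proton therapy**.

When a proton plan is re-optimized on the anatomy of the day, the daily
structures are usually produced by deformable image registration (DIR).
Different DIR algorithms disagree with each other and with what a physician
would draw, and correcting contours by hand is the main bottleneck of online
adaptation. This package implements, on fully synthetic phantoms, the
comparison of six ways of dealing with that uncertainty during spot-weight
optimization:

| strategy | daily structures used for optimization |
|---|---|
| `reference` | the ground-truth ("clinical") contours |
| `single_dir_k` | the k-th DIR-propagated contour set, uncorrected |
| `multi_dir` | all K propagated sets in parallel (worst-case/minimax) |
| `conservative` | target = intersection (stereotactic) or union (coverage) of the K sets; organs = union |
| `probabilistic` | exact-level agreement substructures (33/67/100% for K = 3), objective weights scaled by the agreement fraction k/K |
| `no_adaptation` | none - the initial plan is recomputed on the daily anatomy |

Every plan is evaluated on the **clinical** structures with a clinical
constraint list (e.g. `V47.5Gy > 95%`, `stomach V33Gy < 1 cc`,
`brainstem max < 54Gy`). Plan quality is summarised by a violation-sum
score in arbitrary units (au),

```
score = sum over violated constraints of |C - Cref|
```

where `C` is the evaluated metric and `Cref` its limit, in native units
(percentage points, cc, Gy), so a brainstem maximum of 55 Gy against a
54 Gy limit contributes 1 au. Scores are reported as differences to the
`reference` adaptation of the same fraction, aggregated as mean/min/max per
strategy and anatomy template.

The spot-weight optimization is worst-case (minimax) over the
cross-product of structure-set alternatives and setup/range error
scenarios (nominal, six 3 mm shifts, two 3% range scalings):

```
minimize over w >= 0 of max_s F_s(D_s w),   F = weighted sum of quadratic
one-sided dose penalties and quota-based DVH penalties
```

solved by L-BFGS-B on an annealed log-sum-exp smoothing of the maximum.
Dose comes from an analytic spot-scanning model (Bragg depth-dose in
water-equivalent depth times a lateral Gaussian) assembled into sparse
influence matrices. Everything upstream - phantoms, per-fraction anatomical
change, and the simulated DIR contour ensembles - is generated by seeded
code; no external data are needed.

## Worked example

```r
library(adaptIMPT)

ph    <- generatePhantom(phantomSpec("abdomen", gridShape = c(36, 36, 36)))
spots <- placeSpots(ph, templateBeams("abdomen"))
infl  <- lapply(scenarioSet(), function(s) buildInfluence(ph, spots, s))
cons  <- templateConstraints("abdomen")
plan  <- optimizeInitialPlan(ph, cons, infl, spots, nFractions = 5)
dose  <- computeDose(infl[[1]], planWeights(plan), nFractions = 5)
scorePlan(evaluateConstraints(dose, clinicalStructures(ph), cons))
```

```
Plan-quality score: 0 au ( 0 violated constraints )
```

The robustly optimized stereotactic plan meets the full abdominal
constraint list on the planning anatomy — target coverage
(`V47.5Gy > 95%`) together with every organ hard limit — so its score is
0 au; scores become positive when daily anatomical change and uncorrected
propagated contours enter. A full comparative study is one call:

```r
study <- runStudy(studyConfig(seed = 1))
study$aggregate                     # mean/min/max score difference per strategy
sensitivityAnalysis(study$contributions)  # rankings under score-weight multipliers
```

On the default seeded cohort the reference adaptation is best (score
difference 0 by construction), no adaptation is worst, and the
correction-free strategies lie in between.

## Package layout

- `R/phantom.R`, `R/fields.R`, `R/dirsim.R` - synthetic cohort: anatomy
  templates, displacement fields, per-fraction change, simulated DIR
  contour ensembles
- `R/structures.R`, `R/metrics.R` - contour-ensemble algebra, DVH metrics
- `R/dose.R` - analytic proton dose engine, scenarios, influence matrices
- `R/objectives.R`, `R/solver.R`, `R/strategies.R` - penalty terms, minimax
  solver, the six strategies
- `R/constraints.R`, `R/scoring.R` - constraint dialect, plan-quality score,
  sensitivity analysis
- `R/study.R`, `R/io.R` - cohort orchestration, NIfTI/MTX/JSON I/O

See the methods vignette (`vignettes/adaptive-structure-uncertainty.Rmd`)
for the model assumptions, parameter choices and limitations.
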