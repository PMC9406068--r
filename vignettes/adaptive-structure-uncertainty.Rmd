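---
title: "Contour-propagation uncertainty in online adaptive proton planning: models and methods"
author: "adaptIMPT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-propagation uncertainty in online adaptive proton planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Online adaptive proton therapy re-optimizes the spot weights of an IMPT plan
on the anatomy of the day. The daily structures are usually propagated from
the planning image by deformable image registration (DIR), and different DIR
algorithms produce visibly different contours — all broadly plausible, none
identical to what a physician would draw. Manually reviewing and correcting
contours takes minutes that an online workflow does not have. The question
this package studies is: **how much plan quality is lost when the manual
correction step is replaced by an automatic way of handling the contour
uncertainty inside the optimization itself?**

Six strategies are compared. *Reference adaptation* optimizes on the
ground-truth clinical contours (the best case). *Single-DIR adaptation*
uses one propagated contour set uncorrected. *Multi-DIR adaptation* runs a
worst-case optimization over all K propagated sets in parallel.
*Conservative adaptation* combines the ensemble into one set — the target
intersection under a stereotactic prescription (organ limits outrank
coverage, so the smallest plausible target is treated with the largest
plausible organs), the target union under a coverage-first prescription;
organs always take the union. *Probabilistic adaptation* partitions each
structure into exact agreement substructures (for K = 3: voxels claimed by
all three sets form the 100% level, by exactly two the 67% level, by one the
33% level) and scales each objective's weight by the agreement fraction
k/K. *No adaptation* recomputes the initial plan on the daily anatomy
without re-optimization (the worst case). Every plan, however it was
optimized, is **evaluated on the clinical structures**.

Because no clinical data ship with the package, the entire study runs on
synthetic phantoms. The synthetic cohort is first-class, tested code: its
generators define the study conditions.

## Synthetic cohort

**Phantoms.** Two analytic anatomy templates are rasterized onto a voxel
grid (ellipsoids, z-axis cylinders, paired ellipsoids). The
*abdomen* template (240 mm box) is a stereotactic pancreas/liver-like case:
a ~63 cc CTV surrounded by stomach, small and large bowel, an abutting
duodenum, spinal cord, paired kidneys, and a ~1340 cc liver that contains
the CTV; the liver mask excludes the CTV and duodenum, mirroring the
clinical "liver minus GTV" evaluation volume. The liver volume is chosen
anatomically realistic (adult livers are roughly 1400–1700 cc) so that the
"spare 700 cc of liver below 15 Gy" rule is demanding but satisfiable, as
it is for the patients such constraint sets are written for. The
*head-and-neck* template (192 mm box) has nested high-risk (~82 cc) and
low-risk (~280 cc) CTVs, brainstem, spinal cord ending below the brainstem,
pharyngeal constrictors, larynx and paired parotids. CTV volumes fall
inside the ranges reported for the clinical indications the templates
emulate. Densities are relative stopping powers: air 0.001 outside the
external contour, soft tissue 1.0 inside, mild organ contrast (liver 1.05,
cord 1.04, larynx 0.95). Distinct phantoms of one template are produced by
a seeded jitter of shape centres (SD 3 mm) and radii (SD 6%).

**Per-fraction change.** One smooth displacement field deforms the density
grid and every structure (so image and contours can never disagree): a
rigid shift (fixed plus random, SD 2 mm per axis), a Gaussian-smoothed
random field (per-component SD 6 mm, correlation length 40 mm), an optional
local target volume rescaling, and for head-and-neck an affine shrinkage of
the whole anatomy toward the grid centre (default 15% volume loss,
emulating multi-week weight loss — the driver of the large non-adapted
plan degradation in that site). Warping is pull-back with trilinear
interpolation; masks are transported as level sets thresholded at 0.5,
which avoids the single-voxel holes of nearest-neighbour sampling and
reproduces integer-voxel translations exactly.

**Simulated DIR ensembles.** The registrations themselves are *not*
re-implemented. Each emulated algorithm warps the ground-truth contours
with a systematic bias field plus an independent random field (defaults
2 mm and 1 mm amplitude, 20 mm correlation length). The shared-smoothness
construction reproduces the qualitative observation that intensity-based
DIR algorithms tend to be closer to each other than to physician contours,
while still letting the ensemble union miss some clinical voxels — the
failure mode that motivates evaluating on clinical structures. Each
simulated structure must agree with the clinical contour within a Dice band
(default 0.70–0.995); a draw outside the band is re-drawn with a perturbed
seed up to 8 times, then errors. No published Dice/Hausdorff statistics
exist for the setting emulated here, so the noise amplitudes are free
configuration parameters chosen to produce visually plausible
disagreement; the band guarantees "reasonable" contours and excludes both
outliers and the degenerate perfect copy.

## Dose model

A deliberately simple spot-scanning model — the study's logic needs
qualitatively correct depth-dose behaviour, not a clinical engine. Spot
dose is `bragg(rangeScale * WED(x + shift)) * Gaussian(lateral distance)`.
The water-equivalent depth (WED) is the cumulative stopping-power line
integral along the beam (an exact cumulative sum for the axis-aligned
default beams, ray marching otherwise). The Bragg curve is an analytic
shape: an asymmetric Gaussian peak at the nominal range (7% proximal, 1.2%
distal width) over a logistic entrance plateau at 35% of peak — single
maximum at the range, entrance in the 20–60% band, under 1% of peak beyond
1.05 ranges. Spots are lattice-placed (abdomen: 10 mm lateral / 8 mm
layers / sigma 8 mm; head-and-neck: 14 / 10 / 9 mm) over the target dilated
by an 8 mm margin, each beam separately; every target voxel lies within
half a lattice pitch of a spot. Influence matrices (spots x voxels, dose
per unit weight per fraction) are sparse, with entries below 1% of a spot's
maximum dropped. The robustness model is the common 9-scenario set:
nominal, six axis-aligned 3 mm setup shifts, two 3% range scalings
(configurable to the 21-scenario cross-product; whether a planning system
combines structure-set alternatives and error scenarios multiplicatively is
not documented anywhere we know of, so the cross-product is the default and
is configurable). Dose is scored in Gy-RBE with the constant RBE folded
into the prescriptions; plans are optimized and evaluated as total-course
dose (fraction dose x 5 for the 50 Gy-RBE stereotactic prescription,
x 30 for the 70/54 Gy-RBE head-and-neck prescription) so clinical limits
apply directly.

## Optimization

Constraint rows become standard penalty terms: coverage rows
(`V(d) > p%`) become quadratic underdose penalties at level d (the smooth
standard surrogate; the quota-based `dvh_lower` penalty is implemented and
tested but not the default mapping), hot-spot rows quota-based `dvh_upper`
penalties, `mean`/`max` rows their one-sided penalties, and the liver
sparing rule a `dvh_upper` with quota "structure volume minus the required
spared volume". Published tables give priorities, not weights, so *hard*
constraints get 10x the optimization weight of *soft* ones (configurable);
both score identically at evaluation time. A mild target dose cap
(max-dose at 60 Gy-RBE abdomen / 76 Gy-RBE high-risk CTV), identical
across strategies, prevents unconstrained interior hot spots. Voxels
claimed by several structures contribute to all their terms, unsupervised.

The worst case is the scenario-wise maximum of the composite objective
(objective-wise minimax, not voxel-wise). The solver smooths the maximum
with a log-sum-exp of temperature tau (initialised at 20% of the starting
objective, annealed by 0.2 per stage over 3–4 stages) and minimizes each
stage with bound-constrained L-BFGS; a stage result is accepted only if the
*unsmoothed* maximum decreased, so the recorded history is monotone. A
projected-gradient variant was tried first and stalled an order of
magnitude short of the optima L-BFGS reaches on the same problems.
Initial weights are uniform, scaled so the mean target dose matches the
highest coverage level — deterministic, shared by all strategies.
Identical structure sets deduplicate, so multi-DIR with K identical sets
*is* the single-DIR problem; with zero anatomy change and zero DIR noise
every strategy's problem (and hence its solution and score) collapses onto
the reference plan's exactly, which the test suite asserts.

## Scoring

A constraint is violated when its evaluated value exceeds an upper limit or
falls short of a lower one; a value exactly at the limit is *not* a
violation (the worked examples imply contributions come from exceedance
only). Violations contribute `|C - Cref| * weight` in native units —
percentage points, cc, Gy summed into arbitrary units, unit weights by
default. `V(d)` counts voxels with dose >= d; the closed threshold is a
convention fixed here because published tables do not state one. The
maximum-dose metric is the maximum voxel dose (no near-max volume
convention is given in such tables; the simplest testable choice). For the
nested head-and-neck CTVs the low-risk hot-spot row (`V57.8Gy < 1 cc`) is
evaluated on the low-risk volume excluding the boost volume plus a 10 mm
margin: with the boost prescribed 70 Gy-RBE inside the low-risk CTV, the
planned dose gradient alone otherwise fills tens of cc above 57.8 Gy-RBE
in every plan, and the row would measure the gradient, not plan quality —
the standard clinical construction for intermediate-dose evaluation
structures. Scores are differenced against the reference adaptation of the
same phantom and fraction to remove the anatomy-dependent baseline, then
aggregated as mean/min/max per strategy and template. The sensitivity
analysis re-weights target-only and organ-only constraints by multipliers
1–10 and reports whether the identities of the best and worst strategies
survive.

## Problem sizes and numerical choices

The default study runs 2 templates x 3 phantoms x 3 fractions on 36^3
grids (6.7/5.3 mm voxels), ~500 spots per abdominal plan and ~1200 per
head-and-neck plan, 9 scenarios, and a 200-evaluation solver budget over 4
annealing stages — sizes chosen so a full comparative study is an
interactive desk-scale computation rather than a cluster job. Unit tests
use 16–32^3 grids. Key tolerances: solver stage acceptance on the exact
maximum; sparsity floor 1% of spot maximum; Dice band 0.70–0.995; warp
threshold 0.5. All randomness flows through explicit integer seeds
(phantom, fraction and DIR-set seeds derive deterministically from the
study seed), and every generator is bit-reproducible given its seed.

## What passing tests do and do not show

The generator emulates geometric change and contour disagreement, not
image formation: there is no CT/MR intensity realism, no registration
algorithm, no breath-hold or intrafraction motion, no density overwrites,
and the dose engine has no nuclear halo, heterogeneity-induced lateral
scatter, or deliverability constraints. Consequently the package can test
the *logic* of the strategy comparison — that the scoring system, the
ensemble combinations and the minimax optimization interact as described,
and that on a cohort with realistic-magnitude changes the reference
adaptation scores best and no adaptation worst — but absolute au values are
properties of the synthetic conditions and are not comparable to scores
computed on patients. The violation-sum score itself is a blunt
instrument: it mixes units, and a plan can trade a large violation of one
constraint against several small ones; it supports ranking strategies, not
judging individual plans.
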