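---
title: "Optimizing leaf-sampling effort under within-crown trait variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing leaf-sampling effort under within-crown trait variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional-trait surveys need trait means that represent a population, but
leaves vary strongly *within* a single tree crown: light, wind and water
status change with height and with depth inside the canopy. If a protocol
samples only, say, sun-exposed outer leaves, its estimate of specific leaf
area (SLA, mm²/mg) or of the magnitude of leaf osmotic potential (π, −MPa)
can be biased relative to the whole-crown mean, and its apparent precision
says nothing about that bias. itvsampler implements a complete workflow for
deciding *how many* trees and leaves to sample and *how* to spread the
leaves over the crown:

1. **Variance partitioning.** A univariate permutational ANOVA (Euclidean
   distance, so sums of squares coincide with classical ANOVA) splits the
   corrected total SS of each trait over a nested/crossed design: quadrat
   (plot), individual nested in quadrat, canopy height class (`a` below
   2.5 m / `b` above), external/internal crown position, and their
   interactions. Per-term variance percentages are SS ratios against the
   total. Significance uses Freedman–Lane permutation of reduced-model
   residuals.
2. **Precision target.** Repeated simple random subsamples of increasing
   size *n* give a mean standard error curve SE(*n*); a one-breakpoint
   segmented regression locates the flex point ψ beyond which extra leaves
   buy little extra precision. The SE the curve attains at ψ becomes the
   precision threshold SE~min~.
3. **Strategy simulation.** Named field strategies (fully random;
   equal individuals per quadrat; leaves stratified over the four
   height-by-position strata; "sun-leaf" protocols restricted to external
   or upper-external strata) are simulated by two-stage sampling without
   replacement over a grid of sampling sizes (individuals × leaves per
   individual).
4. **Selection.** A strategy is admissible when its mean estimate falls
   inside the whole-data 95% confidence interval (accuracy) and its mean
   SE is at or below SE~min~ (precision). Among admissible sizes, the
   *minimum* is the smallest total number of leaves, and the *optimum* is
   the size with the largest one-step drop of the summed standardized
   deviation S = |x̄~size~ − x̄~whole~| / SD~whole~ along the effort-ordered
   sequence — the best accuracy return on additional effort.

## The model behind the synthetic generator

Field data of this shape are rarely at hand when a campaign is being
planned, so the package ships a generator that emulates the hierarchical
structure the analysis assumes. Each leaf-pair observation of trait *t* is

y = μ_t + q_{quadrat} + b_{individual} + h_{h\_class} + p_{position} +
(hp)_{h\_class×position} + (qp)_{quadrat×position} + ε,

with every term's effects drawn i.i.d. zero-mean Gaussian at variance
`fraction × total_sd²`, and fractions summing to one. Interaction terms are
limited to the two that matter for these traits (height-by-position and
quadrat-by-position); the others can be enabled through the configuration.
Azimuthal exposure is assigned by drawing a uniform angle on [0, 360) and
mapping (45, 135] → E, (135, 225] → S, (225, 315] → W, remainder → N; exact
multiples of 45° are a measure-zero case assigned to the counter-clockwise
neighbour.

Default conditions reproduce the calibration population: 3 quadrats with
5/17/12 individuals, 3 leaf pairs per stratum (12 per individual, 408 in
total), grand means 8.02 mm²/mg (SLA) and 3.29 −MPa (π). The default total
SDs (1.5 and 1.1) are derived from the population 95% CI half-widths
(half-width × √408 / t₄₀₇ ≈ 1.49 and 1.08). The default variance fractions
place 43.4% of SLA variance on canopy terms and 43.2% of π variance on
plot/individual terms, split evenly within each group; the even split is a
modelling choice, not an estimate, since no per-term decomposition is
available to calibrate against.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring trees, non-Gaussian trait distributions (both traits are
strictly positive; the generator redraws the residual on the rare row a
Gaussian tail would push non-positive, which at the default means/SDs
affects well under 1% of rows), and any between-trait correlation unless
`trait_cor` is set. Passing tests on synthetic data therefore demonstrates
that the machinery is correct under the assumed variance-components model,
not that any particular field population satisfies that model.

A consequence of drawing Gaussian effects for factors with only two or
three levels: the *realized* dataset mean converges to μ_t in the number of
quadrats and individuals, not in the number of leaves, and single-seed
variance percentages for 1-df terms are chi-square-1 distributed around
their target. Tests of mean convergence therefore use residual-dominated
configurations, and parameter-recovery checks average over seeds and target
many-level terms (the 31-df individual term).

## Numerical and procedural choices

* **Sums of squares.** Terms are represented by cell-indicator blocks
  residualized against the intercept and every contained (marginal) term;
  columns fully absorbed by marginal terms are dropped, so a term's rank is
  its true incremental dimension and aliasing (a factor constant in the
  data) is reported by name. Sequential (Type I) SS in the printed term
  order is the default; extra-SS-given-all-other-terms (partial) is
  available. The design is unbalanced across quadrats, so the two differ
  slightly; they coincide on balanced layouts, which the tests exploit.
* **Pseudo-F.** Every term is tested against the residual mean square: all
  factors are treated as fixed, and percentages are SS ratios, not REML
  variance components.
* **Permutation scheme.** For each term, the reduced model holds all other
  terms; its residuals are permuted and added back to its fitted values,
  and the term's extra-SS F statistic is recomputed. p = (1 + #{F* ≥
  F_obs}) / (1 + n_perm), the add-one convention. The permutation unit is
  the individual leaf observation. Defaults: 999 permutations, α = 0.05.
* **Precision curve.** Sampling is without replacement within a replicate;
  replicates (default 4999) are independent. SE = SD/√n without
  finite-population correction, summarized across replicates by the
  arithmetic mean. n = 1 carries no SE and is excluded (the grid starts at
  2). The segmented fit uses a grid-search initialization over interior
  grid points followed by iterative linearization on the gap coefficient
  (update ψ ← ψ + γ̂/β̂₂, convergence |Δψ| < 1e-8, at most 100 iterations);
  non-convergence falls back to the best grid point, flagged. A curve with
  no detectable slope change is flagged non-identifiable rather than
  given an arbitrary breakpoint. One breakpoint only; the fit is applied
  to the mean-SE-per-n curve, not to all replicate SEs jointly.
* **SE~min~.** Two flex values are reported: the broken-line fit evaluated
  at ψ and the observed curve interpolated at ψ. The pipeline uses the
  curve value: on a steeply convex SE curve the broken-line vertex dips
  well below any SE actually attainable at ψ, while the curve value is the
  precision a sample of ψ leaves really delivers (and is consistent with
  SD/√ψ). An analogous CV curve and breakpoint are available for an
  optional dispersion criterion, disabled by default.
* **Strategy registry.** Four unrestricted/stratified designs plus eight
  "sun-leaf" protocol variants with literature preset sizes (minimum 5
  leaves × 5 individuals, preferred 4 × 10). The external-only `cor`/`per`
  pairs share those presets; the registry is a plain named list extensible
  with `strategy_spec()`. Stratified allocation splits leaves as evenly as
  possible over the allowed strata with the excess assigned in the fixed
  order aE, aI, bE, bI; per-quadrat allocation assigns the remainder in
  quadrat label order. Both rules are deterministic so any replicate is
  exactly reproducible. Feasibility is assessed against the worst-case
  individual, so a feasible cell can always be completed regardless of the
  stage-1 draw; infeasible cells are recorded as data, not errors.
* **Screening level.** Strategy-level screening aggregates each strategy's
  per-size means and SEs by the median (a box-plot reading of the
  per-strategy distributions); a switch to the mean is provided. CI
  membership is closed — a mean exactly on a bound passes. Admissibility
  requires every trait to pass. The multi-trait score is an unweighted sum
  of per-trait S.
* **Optimum rule.** "Best compromise" is operationalized as the largest
  single-step decrease of sum-of-S between consecutive admissible sizes
  ordered by total leaves, ties to the smaller effort. A global-minimizer
  alternative was considered and rejected: sum-of-S generally keeps
  drifting down noisily with effort, so the global minimum degenerates to
  "sample almost everything", while the largest-drop rule finds the elbow.
* **Reproducibility.** A single master seed spawns fixed substreams per
  stage and per grid cell (`seed + 1000003·cell mod 2³¹−1`), so any cell
  can be rerun in isolation; the pipeline writes a manifest recording the
  configuration and derived seeds, and a rerun with the same configuration
  is bit-identical.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script scale replicate counts to the
question being asked rather than running everything at survey scale: the
null-calibration study uses 1000 simulated 72-leaf datasets at 199
permutations; parameter recovery averages 20 study-sized datasets;
precision-curve calibration uses 4999 replicates on coarse size grids; and
the strategy grid in the acceptance script runs the full 34 × 12 size grid
for all twelve strategies at 199 replicates. These sizes give Monte-Carlo
noise comfortably below the tolerances being asserted.

## Known limitations

* The PERMANOVA is univariate per trait; no joint multivariate distance
  analysis, and no distances other than Euclidean.
* All factors are fixed; no mixed-model (REML) variance components.
* No cost model: "effort" is the total number of leaves, with no
  distinction between visiting a new tree and picking another leaf.
* Bootstrap confidence intervals on ψ are not implemented.
* Three of the fifteen strategies compared in the original field study are
  not reconstructable from the published text; the registry carries the
  twelve that are, and accepts user definitions for the rest.
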