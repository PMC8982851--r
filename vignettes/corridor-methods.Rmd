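---
title: "Methods: multi-species corridor modelling with corridors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-species corridor modelling with corridors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridors)
```

## The problem

Wildlife corridors are usually designed for one species at a time, but land
set aside for a single species rarely serves a whole assemblage. `corridors`
implements a multi-method workflow for delineating corridors between two
terminal reserves for several species at once: per-species habitat
suitability is estimated from presence records, converted to landscape
resistance under two alternative scalings, run through two connectivity
models (least-cost and circuit theory), and the resulting per-species
products are compared to ask which single species — or which multi-species
composite — best predicts connectivity for the rest of the assemblage.

Every stage is driven from a seeded synthetic-landscape generator, so the
full pipeline is testable end-to-end without any field data.

## Model pipeline

### Habitat suitability

Per-species suitability is estimated by an ensemble of presence/absence
learners. The workflow is:

1. **Collinearity screen** (`collinearity_screen`). All pairwise Pearson
   correlations between predictor layers over jointly valid cells are
   reported; pairs with |r| above 0.7 (the customary screening threshold)
   are flagged. Layers are never dropped automatically — the screen is
   advisory, since variable choice is a scientific decision.
2. **Geographic thinning** (`thin_points`). Presences are visited in a
   seeded random order and kept only if no previously kept point lies
   within the minimum distance (default one cell, 1000 m). The output
   satisfies the min-distance property exactly. This counters spatial
   sampling bias from clustered records such as dung piles along a single
   heavily used path.
3. **Pseudo-absences** (`generate_pseudo_absences`). Background points are
   drawn uniformly without replacement from valid cells not containing a
   presence — either a fixed number (`random`) or one per presence
   (`random_equal`, the default for the pipeline).
4. **Ensemble fitting** (`fit_ensemble`). Each learner family is evaluated
   by repeated stratified holdout: by default 10 repetitions of a 70%
   train / 30% test split, preserving the class ratio in both parts (an
   unstratified split can produce a single-class evaluation set at small
   n, which has no defined AUC). Discrimination is measured by rank-based
   (Mann–Whitney) AUC with ties counted one half. Families whose mean
   holdout AUC reaches the retention threshold (default 0.90) are
   retained, refitted on all data, and combined as an AUC-weighted mean of
   predicted probabilities. If no family qualifies the fit aborts with an
   instruction to lower the threshold — inventing a fallback ensemble
   would silently change the stated contract.

The default learner registry holds four families: logistic regression
(`stats::glm`), boosted regression trees (`xgboost`, depth 3, learning
rate 0.1, 60 rounds, minimum child weight 5, exact split search — the
histogram approximation is unnecessary at these sample sizes and can place
split points inside a class region), a probability random forest
(`ranger`, 300 trees), and a "maxent-like" exponential model implemented
as lasso-regularised logistic regression on linear plus quadratic features
(`glmnet`, penalty chosen by internal 5-fold cross-validation). The
registry is extensible: any object with `fit(x, y, seed)` and
`predict(model, x)` entries can be passed through the `registry` argument.

Per-predictor contributions are estimated by permutation importance: the
drop in full-data AUC when one predictor's values are permuted, floored at
zero and normalised to sum 100. Permutation importance is model-agnostic,
which keeps the report comparable across families.

**Stacking** (`stack_suitability`) sums the per-species probability maps
cell-wise into a multi-species habitat index on [0, S] for S species.

### Resistance scaling

The linear transform anchors the cost scale
(`linear_resistance`):

$$ \mathrm{cost} = (1 - \mathrm{HS}) \times 100 + 1 $$

so a 1-km cell of suitability 1.0 costs 1 cost-weighted km to cross and a
cell of suitability 0.01 costs 100. The non-linear variant
(`nonlinear_resistance`) squares the linear cost (range [1, 10201]),
penalising poor habitat much more steeply while preserving the ranking of
cells — both transforms are strictly decreasing in suitability, so the two
surfaces have Spearman correlation 1 by construction.

The stacked map is divided by S (`normalize_stacked`) before either
transform. Division by S is the only rescaling that keeps the 1-to-101
cost anchors meaningful for the multi-species surface; whether to rescale
or clamp was genuinely open, and rescaling was chosen because clamping
would saturate most of the landscape for any assemblage with even moderate
average suitability.

### Connectivity

Valid cells are graph nodes. Moves to the 8 neighbours carry cost
$\frac{r_i + r_j}{2} \cdot d$, with $d$ the cell length for rook moves and
$\sqrt{2}$ times that for diagonal moves (4-connectivity is available in
configuration). The two reserves are contracted to supernodes with zero
internal cost: the parks are endpoints of movement, not contributors to
traversal cost.

**Least-cost branch** (`cost_distance`, `least_cost_corridor`).
Cost-weighted distance (CWD) from each terminal is an exact shortest-path
computation (Dijkstra, via `igraph`). The normalized corridor surface is
$\mathrm{CWD}_A + \mathrm{CWD}_B - \mathrm{LCP}$, zero along every optimal
path. The binary "10% corridor" keeps the lowest 10% of corridor cells *by
area*; slicing by area (rather than at a fixed cost ratio) makes corridor
extents comparable across species, which the overlap statistic requires. A
cost-ratio slice (`mode = "cost_ratio"`) is available. Ties at the
quantile boundary are all included. Reserve cells are excluded from the
corridor surface before slicing: with contracted terminals every reserve
cell has corridor value exactly 0, so leaving them in would let the
reserves consume the entire area budget and the sliced "corridor" would
largely map the parks themselves rather than the land between them.

**Circuit branch** (`circuit_solve`). Each edge is a resistor with
resistance equal to its traversal cost. With the source supernode fixed at
voltage 1 and the ground at 0, the interior Kirchhoff equations form a
reduced graph-Laplacian system — sparse, symmetric, positive definite —
solved with `Matrix`. Per-cell current is half the sum of absolute
incident edge currents, reported per unit of injected current so that the
current map is invariant to a uniform rescaling of the resistance surface
(only the pattern of flow, not its absolute magnitude, carries
information about movement). Effective resistance is the reciprocal of the
total source outflow of the unit-voltage solution. Disconnected terminals
return an explicit infinite-resistance result rather than an error, since
disconnection is a legitimate scientific finding.

Numerical policy: graph construction and the resistance transforms are
exact; solver stages (shortest paths, linear solves) are reproducible to
1e-8 relative tolerance. Effective resistance can never exceed the
least-cost path cost (resistance distance is dominated by any single
path), and the tests assert this on every fixture.

### Comparison layer

Continuous products (suitability, current, corridor surfaces) are compared
by Pearson correlation over jointly valid cells (`map_correlation`);
binary corridor masks by percent overlap (`percent_overlap`). Overlap is
the symmetric Jaccard percentage $100\,|A \cap B| / |A \cup B|$: the
statistic's denominator was genuinely open, but with equal-area corridor
slices $|A| \approx |B|$ and all conventions nearly coincide; the
asymmetric convention (mean of both directed overlaps) is available
behind a flag. `proxy_ranking` orders labels by their mean pairwise value
against single-species labels — the stacked multi-species map is ranked
itself but never counted among the averaging targets, so single-species
and stacked candidates are judged against the same reference set. Exact
ties are broken alphabetically and flagged.

## The synthetic landscape

`make_predictor_stack` builds two kinds of predictor:

- **smooth fields** — Gaussian-filtered white noise (kernel sd 5 cells by
  default), the simplest stationary stand-in for vegetation indices and
  land-cover fractions;
- **distance fields** — exact Euclidean distance from a few seeded random
  feature points, mimicking distances to settlements, rivers or reserves.

All layers are standardized to zero mean and unit variance over valid
cells. Species are defined on the log-odds scale
(`species_spec`): suitability is the logistic of a linear combination of
predictors, so the generating truth is known exactly and recovery can be
measured. `sample_transect_presences` emulates single-visit line-transect
sampling: parallel north–south transects (default spacing one cell, i.e.
every column at the 1-km default) intersect cells, and each intersected
cell yields a presence with probability `detection_scale × truth`,
jittered within the cell. Detection is Bernoulli per cell;
perpendicular-distance detection functions are deliberately out of scope.

The default pipeline configuration (`default_config`) uses a 60 × 60 grid
of 1-km cells (a landscape of the same order as a ~1280 km² study area),
seven species whose coefficients are drawn i.i.d. normal with sd 1.5 on
the log-odds scale, a shared intercept of −1 (mean suitability ≈ 0.3, so
per-species presence counts land in the tens-to-hundreds typical of
ground-transect surveys), and two corner reserves each covering ~5% of the
grid. When `generalist = TRUE` the last species is the *niche centroid*:
its coefficients are the mean of the others'. A habitat generalist whose
preferences average the assemblage is the pattern a good proxy species is
expected to show, and the Monte-Carlo tests confirm that this species is
the best single-species connectivity proxy in ≥80% of seeded runs.

`plant_corridor_landscape` builds the one fixture whose answer is known by
construction: an L-shaped channel of high suitability (contrast 10 against
the matrix) connecting the two corner reserves. Its channel cells are
recorded, and the tests verify that the least-cost path stays inside the
channel and the 10% corridor slice recovers ≥95% of it.

What the generator does **not** emulate: anisotropy and directional
structure in real land cover, spatially varying detection, temporal
replication (the sampling model is one visit in one season), observer
error in species identity, and real geography (lakes, roads, settlement
clusters). Passing tests therefore demonstrate correctness of the
machinery and recoverability under the stated statistical structure — not
that any particular real landscape would yield the same proxy species.

## Design decisions and numerical choices

- **Seed fan-out.** One run seed is hashed with each stage label
  (`derive_seed`, a polynomial string hash mod 2³¹−1) so a change in one
  stage's draw count never shifts another stage's random stream.
- **Ensemble weighting** is by mean holdout AUC (switchable to unweighted).
- **Learner count.** The registry ships four families rather than a larger
  zoo: the scientific claim of interest is the ensemble contract
  (threshold-retained, AUC-weighted combination), not any individual
  algorithm, and each shipped family is a distinct model class (linear,
  boosted trees, bagged trees, regularised exponential).
- **Degenerate inputs.** Constant layers make Pearson correlation
  undefined: the screen reports the pair as undefined rather than
  guessing; `map_correlation` warns and returns `NA`. One-class AUC is an
  error, not 0.5. Empty terminals, overlapping terminals, out-of-range
  suitability and corridor slices on disconnected landscapes all fail with
  explicit messages.
- **Ordering instability across scalings.** The squared transform changes
  pairwise correlations between species' connectivity maps by much more
  than the spacing between mid-ranked species, so the *full* species
  ordering by mean pairwise correlation is not a stable quantity at this
  problem size; the identity of the *top-ranked* proxy is (it agrees
  between scalings in ~95% of seeded runs). The test suite asserts both
  statements separately rather than pretending the stronger one holds.
- **Problem sizes in the tests** (40 × 40 to 60 × 60 grids, 20 Monte-Carlo
  runs, 2–10 holdout repetitions) were chosen so the entire suite runs in
  well under a minute on one core while keeping every statistical
  assertion at ≥3-sigma separation from its threshold.

## Known limitations

- Raster I/O is ESRI ASCII grid only; inputs must arrive aligned (equal
  shape, origin, cell size) — there is no reprojection engine, only
  validation.
- Connectivity is strictly two-terminal; multi-reserve networks and
  randomized shortest paths are out of scope.
- The circuit solve is a direct sparse factorisation; grids beyond ~10⁶
  cells would need an iterative solver.
- Detection-probability modelling (distance sampling) and temporal
  replication are not implemented; presence data are taken at face value
  after thinning.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(seed = 42, shape = c(60, 60))
res <- run_pipeline(cfg, out_dir = "run42")

# which species best predicts the others' connectivity?
res$rankings[["linear.current"]]

# analytic anchors of the resistance transform
linear_resistance(suitability_map(
  raster_grid(matrix(c(1, 0.01), 1, 2)), "anchor"))$grid$values
#>      [,1] [,2]
#> [1,]    1  100
```
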