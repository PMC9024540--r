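---
title: "Methods: ensemble habitat models and niche dynamics in ensdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat models and niche dynamics in ensdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures in `ensdm`, the
assumptions behind them, the defaults and why they were chosen, and the
places where the methodology admits more than one reasonable convention and
the package had to pick one.

## The modeling problem

Species distribution models relate georeferenced presence records to
gridded environmental predictors (typically bioclimatic variables — annual
mean temperature, precipitation of the driest quarter, and so on) to
estimate a habitat-suitability surface, then project that surface onto
altered climate layers to ask how the suitable range will move. Because
true absences are rarely observed for plants surveyed opportunistically,
the standard device is *pseudo-absences*: background cells sampled at
random and treated as absences, with the model interpreted as ranking
habitat rather than estimating true occupancy probability.

No single algorithm family dominates this problem, so the field's standard
practice is an ensemble: fit many algorithms on repeated data splits, keep
the skilful ones, and average. `ensdm` follows that design end to end.

## Data preparation

**Spatial thinning** (`thin_occurrences`). Clustered survey records inflate
apparent prevalence near well-visited sites. Thinning is greedy in input
order: first at most one record per raster cell, then (optionally) a
minimum great-circle distance in km between retained points (haversine, via
geosphere). Greedy-in-input-order is deterministic and idempotent; the
input order is therefore part of the reproducibility contract. The default
distance is 0 km (one-per-cell only) because an appropriate distance is
study-area specific.

**Collinearity filtering** (`correlation_matrix`, `select_uncorrelated`).
Bioclimatic variables are strongly inter-correlated; the conventional rule
keeps a subset whose pairwise Pearson |r| does not exceed 0.75.
Correlations are computed over all valid raster cells of the model-fitting
extent by default (an occurrence-cell option exists): the filter describes
the predictor space the model will see, not just the occupied corner of it.
The reduction of a correlated group to one representative is not unique —
the outcome depends on the order in which variables are considered — so the
filter takes an explicit `priority` order (default: input order) and this
order is the documented reproducibility knob. The retained set is verified
against the threshold before being returned (a certificate, not an
assumption).

**Pseudo-absences** (`sample_pseudo_absences`). Uniform without
replacement over valid, presence-free cells; 10,000 by default, the
conventional background size for regression-type algorithms. Because one
uniform draw is shared by all repetitions (the common default in ensemble
platforms), between-repetition variation reflects the data split, not the
background. Pseudo-absences are down-weighted so total absence weight
equals total presence weight (the "prevalence 0.5" convention): algorithms
then see a balanced problem regardless of background size.

## The nine algorithms

`fit_suite` fits GLM, GBM, GAM, CTA, ANN, SRE, FDA, RF and MAXENT on each
of `reps = 3` stratified 80/20 splits — 27 models. All scorers share one
contract: a map from predictor vectors to [0, 1]. Hyperparameters are fixed
conservative defaults (see `sdm_defaults()`), never tuned per dataset:

* **GLM** — binomial logistic regression with linear + quadratic terms per
  predictor. The quadratic terms matter: a unimodal climatic niche is not
  representable by a monotone linear logistic.
* **GBM** — gradient-boosted trees (xgboost; 150 rounds, depth 3,
  learning rate 0.1, single thread for determinism).
* **GAM** — binomial additive model with thin-plate smooths, k = 4 per
  predictor (mgcv, REML). Small k keeps response curves ecologically smooth.
* **CTA** — a single classification tree (rpart, cp = 0.01).
* **ANN** — one hidden layer of 5 units, weight decay 0.01 (nnet), on
  standardized predictors.
* **SRE** — surface range envelope, implemented natively: the rectilinear
  box between the q and 1−q empirical quantiles (q = 0.025) of presence
  values per predictor; prediction is 1 inside the box on every axis, else
  0. It is the only scorer that is binary by construction.
* **FDA** — discriminant analysis on a linear + quadratic basis expansion
  of standardized predictors (equal priors), a quadratic-basis member of
  the discriminant family.
* **RF** — random forest, 500 trees.
* **MAXENT** — an L1-regularized logistic model (glmnet) on linear +
  quadratic features with cross-validated penalty; a Java-free scorer with
  the same contract as the others. It approximates the maximum-entropy
  model's behavior on these features and is documented as such.

A degenerate training fold (one class) produces a *failed-model record*
with a reason, never an exception: suites degrade gracefully and failed
models are excluded from ensembles.

## Evaluation and ensembles

Each model is scored on its own held-out 20% fold: rank-based (Mann-Whitney,
midrank ties) ROC-AUC, and the true skill statistic
TSS = sensitivity + specificity − 1 maximized over all cutoffs (every
midpoint between consecutive unique scores, plus 0 and 1; the smallest
maximizing cutoff is reported, so ties break toward sensitivity).

`build_ensemble` keeps models with TSS ≥ 0.8 (the conventional
"high-performance" gate; the boundary value 0.80 is kept). Two combiners:

* **committee averaging** — members are binarized at their own TSS-optimal
  cutoffs; the ensemble value is the fraction of members voting "suitable";
* **weighted mean** — continuous member scores averaged with
  TSS-proportional weights (weights ≥ 0, summing to 1).

Both are reported on the integer 0–1000 suitability scale with *half-up*
rounding, so mapped class boundaries are platform-stable. Ensemble-level
AUC/TSS are computed by pooling the members' validation folds: each data row
is scored by exactly the members that held it out (weights renormalized
within that subset). This is a documented convention — the evaluation split
behind published single-number ensemble scores is generally not stated.

**Variable importance** is the permutation measure: importance =
mean over permutations of max(0, 1 − Pearson r(original predictions,
predictions after permuting the variable)); 0 means the model ignores the
variable. Three permutations per estimate by default, with derived
sub-seeds. The per-algorithm table (rows = variables, columns = algorithms
plus their mean) averages over repetitions within an algorithm.

## Range change

Current and future ensemble grids are binarized at the *current* ensemble's
TSS-optimal cutoff (×1000) — the same cutoff for both periods, since the
future map has no observations to re-optimize on. Pixels cross-tabulate
into Loss, Stable, Gain, Absent, with percent loss = 100·Loss/(Loss+Stable),
percent gain = 100·Gain/(Loss+Stable), range change = gain − loss
percentages. Percentages are exact internally and rounded to 3 decimals
only at serialization. The categorical change map is coded −2 loss,
−1 absent, 1 stable, 2 gain. No dispersal constraint is modeled: "gain"
assumes the species can reach newly suitable cells.

## Niche dynamics in PCA-env space

The two periods' environmental backgrounds are pooled, centered and scaled,
and the first two principal components define one shared 2-D environment
space (PCA-env calibrated on backgrounds — not on occurrences — so axes
describe available climate). Occurrence and background densities are
estimated on an R × R grid (R = 100) spanning the pooled background
envelope with Gaussian kernels, normal-reference bandwidth per axis
(`MASS::bandwidth.nrd`; the classical plug-in rule — recorded in output,
not tunable by accident). The occupancy surface z is occurrence density
divided by background density where the latter is positive, normalized to
sum 1; dividing out availability distinguishes preference from abundance of
environments.

Overlap is Schoener's D = 1 − ½ Σ|z₁ − z₂| ∈ [0, 1]. Two permutation
tests, both with p = (favorable + 1)/(reps + 1), reps = 99 by default:

* **equivalency** — pool the occurrence sets, reassign at random to the
  original group sizes, rebuild both z surfaces, recompute D. Alternative
  "lower" by default: small p means lower overlap than interchangeability
  allows, rejecting equivalency. The alternative is overridable because the
  literature uses both readings.
* **similarity** — translate the second niche's observed density so its
  centroid lands on a uniformly drawn background cell (mass wraps at grid
  edges, a torus shift), rebuild z against the unchanged background,
  recompute D. Alternative "greater" by default: small p means the niches
  are more similar than random placement. The shifted entity is the second
  (future) niche; a comparison in the other direction is obtained by
  swapping arguments.

In the full pipeline the "occurrences" of each period are its ensemble-
predicted presence cells (capped at `niche_occ_max`, default 500) and each
period's background is the valid raster cells (capped at `bg_max`, default
10,000), all under derived seeds. Using predicted presences makes the two
periods symmetric — the future period has no observed records by
construction.

## The virtual-species generator

`generate_climate` draws white noise per layer, smooths with a separable
moving-average kernel of width `spatial_range` cells (spatial
autocorrelation), then orthonormalizes the smoothed fields and mixes them
through the symmetric square root of the target correlation matrix —
empirical cross-layer correlations equal the target exactly on a fully
valid grid, and to within a few hundredths under a nodata mask. Everything
is a pure function of the spec and its seed. `true_suitability` defines the
species as a product of independent Gaussian responses on a subset of
layers, rescaled to maximum 1; `sample_occurrences` draws presence cells
without replacement proportional to suitability; `apply_scenario` shifts
layers affinely (offset/factor) with the mask untouched, so valid-cell
counts are conserved across periods.

What the simulator emulates: smooth, cross-correlated climate-like fields
(including |r| > 0.75 pairs to exercise the filter), a unimodal niche,
presence-only sampling, and future layer sets with known contraction or
expansion. What it does not emulate: sampling bias, observation error,
dispersal limits, interactions between drivers, and non-Gaussian response
shapes. Green tests on the simulator therefore certify the machinery —
recovery of a recoverable species — not performance on any real landscape.

**Reference study conditions** (used in the test suite and the acceptance
script): 5 layers on a 120 × 120 grid (0.05° cells), smoothing range 8
cells, 5% nodata; a specialist species driven by two layers with Gaussian
widths 0.25 (in layer-sd units) — about 3% of the landscape has true
suitability above 0.5 — 300 presences, 2,000 pseudo-absences, 3
repetitions. These sizes keep a full 27-model fit under ten seconds while
leaving the ensemble's skill (held-out AUC ≈ 0.95, TSS ≈ 0.85) well clear
of the 0.9/0.8 bars the package asserts for a clean recoverable species.
The type-I-error calibration of the equivalency test uses 500–600 simulated
null datasets with 99 permutations each on a 30 × 30 grid.

## Numerical and I/O choices

* Raster layers are exchanged as single-band ESRI ASCII grids (`.asc`) —
  the SDM field's standard plain-text raster format — plus a JSON manifest
  (layer order, affine georeference, CRS, nodata). Values serialize at
  `%.17g`, so a write→read round trip is value-exact.
* Cell membership uses half-open intervals; a point exactly on an interior
  grid edge belongs to the lower-index cell. Coordinates are WGS84 lon/lat.
* Rounding to the 0–1000 scale is half-up (`floor(x + 0.5)`), never
  banker's rounding.
* Sub-seeds for stages, repetitions and permutations derive from one global
  seed by fixed integer arithmetic below 2³¹; no stage consumes unseeded
  randomness. Identical config + seed reproduces byte-identical statistics
  files.
* Zero-variance layers are dropped (with a warning) before correlation or
  PCA; constant predictions yield importance 0 with a warning rather than
  NaN.

## Known limitations

* The MAXENT and FDA scorers are same-contract members of their families,
  not bindings to the Java MaxEnt or the archived flexible-discriminant
  implementations; individual-algorithm scores should not be compared
  against published runs of those tools, though the ensemble machinery is
  indifferent to this.
* The similarity test's torus shift relocates density mass without
  reshaping it; niches that structurally resemble their background are
  flagged as "similar" by construction — a property shared by the standard
  shift-based null.
* Range-change percentages are undefined when the current range is empty
  (returned as NA with a warning).
* No spatial block cross-validation: random splits can be optimistic under
  strong spatial autocorrelation, which is one reason the gate is set at
  TSS 0.8 rather than lower.
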