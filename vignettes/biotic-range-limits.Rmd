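---
title: "Testing biotic range limits with presence-background models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing biotic range limits with presence-background models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioticrange)
```

## The question

Climate envelopes usually explain where a species *could* live; they often
fail to explain where it *stops*. A recurring case is a consumer whose
southern (or northern) range margin tracks the range edge of a single
resource species — for example a montane bird whose distribution ends
where a food-plant's distribution ends, even though climatically suitable
habitat continues beyond. `bioticrange` packages the complete workflow for
testing this hypothesis with presence-background species distribution
models (SDMs):

1. fit three models from the same occurrence data — climate-only
   ("abiotic"), resource-layer-only ("biotic only"), and climate plus a
   binary resource layer ("abiotic + biotic");
2. evaluate all three with a six-index, threshold-sweep suite that puts
   special weight on *commission* (overprediction beyond the observed
   range);
3. ask whether the combined model (a) overpredicts less and (b) assigns
   the resource layer the dominant share of explanatory credit.

If the answer to both is yes, the data support a biotic range limit; if
adding the resource layer buys nothing, the climate-only explanation
stands (the Eltonian-noise expectation).

## The model

The SDM core is a from-scratch maximum-entropy (Maxent-style)
presence-background model. Given presence points $x_1,\dots,x_m$ and a
background sample $B$, the model is the Gibbs distribution over the
background,

$$P_\lambda(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z_\lambda},
\qquad Z_\lambda = \sum_{b \in B} \exp\Big(\sum_j \lambda_j f_j(b)\Big),$$

with coefficients chosen to minimize the L1-penalized negative mean
presence log-likelihood

$$J(\lambda) = -\frac1m \sum_i \log P_\lambda(x_i)
 + \sum_j \beta_j |\lambda_j|.$$

The features $f_j$ are the usual Maxent classes — min-max-scaled linear
and quadratic terms, scaled pairwise products, forward and reverse hinges
at 20 background quantiles per variable, and untransformed indicators for
binary predictors — all scaled by background constants so every feature
maps the background into $[0,1]$. Which classes are enabled follows the
presence-count schedule (linear below 10 presences; quadratic from 10;
hinge from 15; product from 80). A binary resource layer enters as a
single categorical indicator, never expanded.

Three design choices deserve explanation:

* **Normalization sample.** By default the presence samples join the
  background for $Z$ (`add_samples_to_background = TRUE`). With a small
  background (250 points) and hundreds of hinge features, the presences
  are otherwise linearly separable from the background in feature space
  and the likelihood is unbounded. Including the samples — the default
  in the reference Maxent implementation — bounds the objective without
  ad-hoc coefficient caps. Normalization-over-background-only remains
  available, and is what the closed-form unit tests use.
* **Optimizer.** Coefficients are fitted by *greedy* coordinate descent:
  at each step the feature whose local second-order model promises the
  largest penalized gain is updated (Newton step, soft-thresholding,
  exact-objective step halving). Greedy order matters: the training
  trace of per-step objective gains is what the percent-contribution
  heuristic consumes, and credit for shared signal should go to the
  feature that buys the most improvement first, as in Maxent's own
  sequential-update algorithm. The problem is convex, so the final
  coefficients do not depend on this choice — only the gain attribution
  does. Convergence is declared when the best available single-step gain
  falls below `tol` (default 1e-6; `max_iter` 2000 steps).
* **Penalties.** $\beta_j = c(\text{class}) \cdot
  \mathrm{sd}_B(f_j)/\sqrt{m} \cdot \beta_{\text{mult}}$ with class
  constants 1.0 (linear, quadratic, product), 0.5 (hinge), 0.25
  (categorical). This is a deliberately simple, documented schedule with
  the qualitative shape of Maxent's defaults; the interpolated tables of
  the Java implementation are not reproduced. The global multiplier
  (default 1) exposes the whole regularization path.

Raw output is $P_\lambda$ normalized over the background sample (sums to
1 there); logistic output is the entropy-calibrated transform
$e^H r/(1 + e^H r)$ with $H$ the entropy of the fitted background
distribution, so the null model scores 0.5 everywhere (implicit
prevalence 0.5).

Variable importance is reported two ways: **percent contribution**
(positive per-step gains credited to the updated feature's source
variables, products split equally, scaled to 100) and **permutation
importance** (drop in training ROC AUC when one variable's values are
shuffled across the combined presence + background rows, floored at 0,
averaged over `n_perm = 5` shuffles, scaled to 100).

## Evaluation

All indices derive from the confusion matrix of test presences versus
pseudo-absences at a threshold $t$, with "predicted present" meaning
score $\ge t$:

* threshold-independent ROC AUC (computed by mid-ranks, i.e. the
  Mann–Whitney statistic with tie correction — checked in the tests
  against exhaustive pair counting);
* the areas under the threshold sweeps of Cohen's kappa, overall
  performance (correct classification rate), the commission rate
  $fp/(fp+tn)$ and the omission rate $fn/(fn+tp)$ — each evaluated on a
  101-point grid (0 to 1 by 0.01) and integrated by the trapezoidal rule
  normalized by the axis span, so a constant curve at $c$ integrates to
  $c$;
* the point-biserial (Pearson) correlation between the 0/1 labels and
  the continuous scores.

Degenerate margins use fixed conventions (commission 0 when $fp+tn=0$,
omission 0 when $fn+tp=0$, kappa 0 when chance agreement is 1), kappa is
never clipped, and a constant predictor reports `NA` correlation. Binary
maps use the smallest grid threshold attaining maximum kappa. The same
250 background points serve as training background and evaluation
pseudo-absences; nothing in the workflow precludes passing a fresh draw,
but the default mirrors a single-background design and is stated here so
the evaluation is interpreted accordingly.

## Occurrence preparation

Records pass an effort filter before any modeling: stationary counts and
specimens are accepted; traveling counts only below 5 km; exhaustive
area counts only below 1 km². Both thresholds are strict — a 5.0 km
traveling count is rejected — and every rejection carries a
machine-readable reason. Accepted records are thinned so all pairwise
great-circle distances are at least 1 km, using randomized greedy
elimination (repeatedly remove one record uniformly among those with the
most sub-threshold neighbors) followed by a restoration pass that makes
the result maximal, best of 100 repetitions. Thinned records are split
75/25 into training and test (test size takes the floor), and background
points are drawn uniformly over valid cells at cell centers, presences
not excluded. All distances are haversine on a sphere of radius
6371.0088 km; no projection is ever applied, because the thresholds that
matter (1 km, 5 km, 20 km) are stated in kilometers and planar-degree
approximations distort at those scales.

The binary resource layer marks a cell as 1 when its *center* lies
within 20 km (inclusive) of any resource-species record. Cell-center
membership is deterministic and resolution-independent; the tests verify
it cell-by-cell against a brute-force haversine sweep.

## The synthetic landscape

Because the original climate rasters are a download-scale input, the
package ships a generator that emulates the study system end to end on a
0.1° grid over 82°W–69°W, 7°S–11°N (180 × 130 cells — the full-resolution
analysis would use the same code on finer grids):

* **Climate stack:** 19 layers (the size of a standard bioclimatic set),
  each a random latitudinal/longitudinal gradient plus Gaussian noise
  smoothed with an 8-cell kernel, standardized. Only the first 3 layers
  carry true signal; the other 16 exercise regularization and the
  importance diagnostics against noise.
* **Truth:** suitability is
  $\mathrm{logit}^{-1}(\sum a_i x_i + \sum b_i x_i^2) \cdot
  (\delta\,M + 1 - \delta)$ where $M$ is the resource mask and $\delta$
  the biotic dependence. Defaults $a = (1.0, -0.7, 0.5)$,
  $b = (-0.6, -0.4, -0.2)$, intercept 0 give a broad unimodal climate
  envelope, so that with $\delta = 1$ the range is limited chiefly by
  the resource — the biological situation under test. $\delta = 0$ is
  the negative control.
* **Resource range:** a latent field mixing the leading climate layers
  (weight 0.4) with finer-scale smoothed noise (weight 0.6, 4-cell
  kernel — the resource's partly edaphic, patchy niche is deliberately
  not a function of the climate stack), cut hard at the equator and
  thresholded to occupy 700 cells (~6·10⁴ km², a compact montane-endemic
  range). Fixing the occupied *area* rather than the latent threshold
  keeps the study conditions comparable across seeds. The generator also
  reports the resource-free cells whose abiotic suitability exceeds the
  within-range median — the region a climate-only model is prone to
  overpredict, whose southern part is the analog of suitable terrain
  beyond the hard range margin.
* **Occurrences:** 319 records drawn cell-wise proportional to
  suitability. In the pipeline they cluster at 120 observation sites
  (records scatter within 0.3 km of their site), emulating the site
  fidelity of citizen-science archives; 1-km thinning then collapses the
  data to roughly one record per site, reproducing the
  hundreds-to-~115-to-~85-training trajectory of real archives.
  Protocol metadata are assigned (40% stationary, 30% traveling with
  distances uniform on 0–8 km, 20% area counts 0–2 km², 10% specimens)
  so the effort filter rejects a realistic share. Resource records (117)
  are herbarium-style: specimen protocol, placed by farthest-point
  sampling over the occupied cells, the way a curated collection
  database covers a range rather than clustering.

What the generator does **not** emulate: real covariance structure among
bioclimatic variables (real layers are strongly collinear; ours are
independent), elevation and topography, detection failure, georeferencing
error, and spatially biased effort beyond site fidelity. Passing tests
therefore demonstrate that the pipeline recovers the truths *it defines*,
not that any particular real dataset will behave identically.

A separate deterministic generator, `synthetic_reference_occurrences()`,
builds a stand-in for the study's archived occurrence tables (which are
not redistributable here): 319 focal records arranged in 113
sub-kilometer clusters with >2 km between clusters — so *any* maximal
1-km thinning, including the exact maximum-independent-set solution,
retains exactly 113 — plus 117 resource records. The shipped
`inst/extdata/*_synthetic.csv` files are this generator's output and are
labelled synthetic throughout.

## Numerical choices and degenerate inputs

* Points on a cell boundary belong to the cell whose center is nearest;
  exact midpoints go to the higher column (east) and lower row (north)
  index.
* Rasters are ESRI ASCII grids (plain text, north-up, nodata tag);
  points are headered CSV. Write-then-read reproduces values to ~1e-10.
* Constant predictors emit no features (with a warning); a model whose
  every coefficient is shrunk to zero predicts logistic 0.5 everywhere,
  reports zero contributions and an `NA` correlation.
* Thinning of an empty set is an empty set, not an error; a single
  record cannot be partitioned.
* All stochastic steps (generator, thinning, partitioning, background,
  permutation) take explicit integer seeds and restore the caller's RNG
  state.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
0.1° default (23,400 cells, 19 + 1 predictors, ~970 features, 84
training presences, 250 background points); a single three-model
comparison takes a few seconds on one core. The headline check repeats
the comparison across 5 seeds at $\delta = 1$ and 5 seeds at
$\delta = 0$; the recovery check fits 300 presences on a $\delta = 0$
truth and correlates predicted with true suitability over all cells.

## Known limitations

* The L1 penalty schedule is a simplified stand-in for Maxent's
  interpolated defaults; absolute coefficient values differ from the
  Java implementation even where rankings agree.
* Percent contribution is path-dependent by construction and inherits
  the usual caveat about collinear predictors; permutation importance is
  the more robust of the two diagnostics.
* Evaluation reuses the training background as pseudo-absences; indices
  are comparative (between models on identical data), not absolute
  measures of real-world accuracy.
* The commission-based test is one-sided evidence: low commission under
  the combined model is consistent with a biotic limit but cannot, by
  itself, exclude unmodeled correlates of the resource's range.
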