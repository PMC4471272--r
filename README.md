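# bioticrange

Does a biotic interaction — the presence of a single resource species —
limit a consumer's geographic range beyond what climate predicts?
`bioticrange` implements the complete species-distribution-modeling
(SDM) workflow for answering that question with presence-background
data: a from-scratch maximum-entropy model with L1 regularization,
occurrence-record preparation (effort filtering, 1-km spatial thinning,
train/test partitioning, background sampling), a distance-buffered
binary resource layer, a six-index threshold-sweep evaluation suite
emphasizing commission (overprediction), and a synthetic-landscape
generator so the whole pipeline is testable without raster downloads.

The motivating system is a tropical montane bird (the Acorn Woodpecker
in the Northern Andes) whose southern range margin tracks the range
edge of a food plant (the Colombian oak) rather than any climatic
barrier; the package generalizes that analysis into reusable, tested
components.

## The core model

Given presence points `x_1..x_m` and a background sample `B`, the model
is the Gibbs distribution over the background

    P(x) = exp( sum_j lambda_j f_j(x) ) / Z,

fitted by minimizing the L1-penalized negative mean presence
log-likelihood

    J(lambda) = -(1/m) sum_i log P(x_i) + sum_j beta_j |lambda_j|,

where the features `f_j` are the standard Maxent classes (scaled linear,
quadratic, product, hinge at background quantiles, categorical
indicators) and `beta_j` follows a documented per-class schedule scaled
by `sd_B(f_j)/sqrt(m)`. Fitting is greedy coordinate descent with
soft-thresholding; the per-step gain trace feeds the percent-contribution
diagnostic, and permutation importance reports the training-AUC drop
under column shuffling. Predictions come raw (normalized over the
background) or logistic (entropy-calibrated to prevalence 0.5).

Three models are compared on one shared partition and background —
climate-only, resource-layer-only, and climate + resource — with ROC
AUC, the areas under the threshold sweeps of kappa, overall performance,
commission and omission, and the point-biserial correlation. The
hypothesis of a biotic range limit predicts that the combined model
overpredicts less (lower commission AUC) and that the resource layer
dominates both importance diagnostics.

## Worked example

```r
library(bioticrange)

rep <- run_comparison(default_config(delta = 1, seed = 1))
print(rep)
```

```
comparison_report (delta = 1, seed = 1)
     input   accepted    thinned      train       test background
       319        253        112         84         28        250
                              index   abiotic biotic_only abiotic_plus_biotic                best
1                        AUC of ROC 0.9747143   0.9284286           0.9537143             abiotic
2                      AUC of Kappa 0.3088655   0.4146804           0.4197434 abiotic_plus_biotic
3        AUC of Overall Performance 0.8386331   0.9098201           0.9100360 abiotic_plus_biotic
4           AUC of Commission Index 0.1278000   0.0440800           0.0438000 abiotic_plus_biotic
5             AUC of Omission Index 0.4610714   0.5017857           0.5021429             abiotic
6 Pearson's Correlation Coefficient 0.6856000   0.7870876           0.7988998 abiotic_plus_biotic
```

The counts row tracks the data through preparation: 319 synthetic
records, 253 surviving the effort filter, 112 after 1-km thinning, split
84/28 for training and testing against 250 background points. In the
index table the combined model wins the commission row (0.044 vs 0.128):
the climate-only model predicts presence in resource-free terrain that
the combined model correctly rejects. The resource layer also dominates
the combined model's variable diagnostics:

```r
contribution_tables(rep, cutoff = 7.5)$abiotic_plus_biotic
#>   variable percent_contribution permutation_importance
#> 1 resource                 99.6                   94.8

om <- overprediction_map(rep)
attr(om, "n_flagged")            # 320 cells kept by climate, dropped by
attr(om, "free_region_overlap")  # the combined model; 88% of them lie in
                                 # the resource-free but climatically
                                 # suitable region of the ground truth
```

With `delta = 0` (a truth with no biotic dependence) the same pipeline
shows no commission advantage — the negative control.

A synthetic stand-in for the study's archived occurrence tables is
shipped in `inst/extdata/` (`*_synthetic.csv`): 319 woodpecker-like
records whose 1-km thinning retains exactly 113 distinct sites (85
training / 28 test at a one-quarter holdout) and 117 oak-like records,
mirroring the published preparation counts.

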