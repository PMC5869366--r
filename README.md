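# rsfcompare

Dual-framework resource selection analysis for wildlife telemetry: a
classical mixed-effects logistic RSF and a conditional-inference random
forest, fitted to the same use-availability design and compared head to
head.

Resource selection functions (RSFs) contrast *used* locations (GPS fixes)
with *available* locations (random points within a delineated seasonal
range) to quantify which habitat features an animal selects or avoids. The
standard tool is logistic regression with a per-individual random
intercept,

&nbsp;&nbsp;&nbsp;&nbsp;logit P(y = 1) = **x**'β + b_j,&nbsp;&nbsp; b_j ~ N(0, σ_b²),

with AICc all-subsets selection and an uninformative-parameter screen. Its
logit-linear form struggles with humped responses (an optimal elevation
band), thresholds (strong selection within ~1 km of water), and complex
interactions. The machine-learning alternative implemented here is a
conditional-inference random forest — recursive partitioning with
permutation-test split selection, grown on small subsamples drawn without
replacement — whose out-of-bag permutation importance captures main effects
*and* interactions.

The package provides every stage as tested, reusable functions:

* **synthetic data** — spatially autocorrelated landscapes (elevation,
  slope, aspect, distance to water, categorical vegetation) and
  individual-level telemetry sampled from a known true selection surface
  (`gen_landscape()`, `truth_surface()`, `gen_telemetry()`);
* **design** — kernel-density range delineation (99.9% isopleth + buffer),
  1:1 availability sampling, covariate extraction, |r| ≤ 0.65 collinearity
  thinning (`build_design()`);
* **glmm** — IRLS logistic core, Laplace mixed fit, AICc all-subsets and
  the uninformative-parameter screen, standardized coefficients
  (`fit_rsf_glmm()`, `all_subsets()`, `prune_uninformative()`);
* **forest** — conditional-inference forest, OOB prediction, permutation
  importance (`fit_forest()`, `permutation_importance()`);
* **interpret** — partial dependence, the 10×10-bin additive-reconstruction
  RMSE index of bivariate interaction strength, suitability rasters and
  RF−GLMM difference maps (`partial_dependence()`,
  `interaction_strength()`, `project_map()`, `difference_map()`);
* **evaluate** — leave-one-individual-out cross-validation, midrank AUC,
  and the DeLong test for correlated ROC curves (`cross_validate()`,
  `roc_auc()`, `delong_test()`);
* **pipeline** — one reproducible orchestrated run with a serializable
  configuration and checksummed artifacts (`run_config()`, `run_all()`,
  `compare_report()`).

## Worked example

```r
library(rsfcompare)

cfg <- run_config(seed = 42,
                  n_individuals = 15, fixes_per_individual = 120,
                  ntree = 200, fraction = 0.25, cv_ntree = 80)
run <- run_all(cfg)
print(run)
#> <rsf_run>
#>   CV: AUC RF = 0.795 vs GLMM = 0.779 (DeLong D = 3.99, p = 6.6e-05)
compare_report(run)
#> Variable importance (forest) vs standardized coefficients (GLMM):
#>     variable rf_importance glmm_std_coef
#> 1 dist_water       0.11500        -1.170
#> 2       elev       0.02750         0.272
#> 3        veg       0.02680            NA
#> 4 cos_aspect       0.01170         0.320
#> 5      slope       0.00644         0.213
#> 6 sin_aspect       0.00422        -0.082
#> ...
#> Leave-one-individual-out AUC:
#>           model   auc    D       p
#> 1 random_forest 0.795 3.99 6.6e-05
#> 2          glmm 0.779 3.99 6.6e-05
```

Reading the output: the forest's LOIO-CV AUC (0.795) exceeds the mixed
logistic model's (0.779) and the DeLong test says the difference is real
(p ≈ 1e-05) — the expected outcome here, because the simulated truth
contains a humped elevation response and a water threshold that a
logit-linear model cannot express. Distance to water dominates both
importance rankings (it carries the largest single effect), while the
forest additionally recovers the *shape* of the nonlinear responses:
compare `run$pd$elev$forest$grid` against the known truth from
`truth_partial_dependence()`.

Everything is deterministic given the seed; `run_all()` writes CSV tables,
ASCII-grid rasters and an md5-checksummed manifest when `out_dir` is set.

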