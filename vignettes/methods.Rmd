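---
title: "Comparing classical and machine-learning resource selection functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing classical and machine-learning resource selection functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resource selection functions (RSFs) score spatial units in proportion to an
animal's probability of using them. The standard design contrasts *used*
units (GPS telemetry fixes) against *available* units (random points within
a delineated range) with a logistic regression; a per-individual random
intercept absorbs unequal fix counts and between-animal heterogeneity.
Logit-linear RSFs struggle with two structures that are common in real
selection surfaces: non-monotone responses (an optimal band of elevation or
slope, a threshold in distance to water) and interactions between
covariates.

`rsfcompare` implements, side by side, the classical mixed-effects logistic
RSF and a conditional-inference random forest fitted to the same
use-availability design, plus the machinery needed to compare them:
permutation variable importance against standardized coefficients, a
bivariate interaction-strength index, geographic projection with difference
maps, and leave-one-individual-out (LOIO) cross-validation with a DeLong
test on the two correlated AUCs. A synthetic-data module generates
landscapes and telemetry from a *known* selection surface, so every stage is
testable end to end without any field data.

## The models

**Mixed logistic RSF.** For row $i$ of individual $j$,
$\mathrm{logit}\,P(y_i = 1) = \mathbf{x}_i^\top\beta + b_j$,
$b_j \sim N(0, \sigma_b^2)$, fitted by Laplace-approximated maximum
likelihood (`lme4::glmer`, one quadrature point — the conventional default).
Continuous covariates enter standardized; vegetation enters as one-hot
contrasts against the sagebrush reference class; interactions are products
of standardized mains. Model selection is all-subsets by AICc
($-2\ell + 2k + 2k(k+1)/(n-k-1)$, $k$ counting fixed effects plus the
variance parameter) over hierarchical term sets, followed by the
uninformative-parameter screen: a larger model that fails to beat a nested
submodel by 2 AICc units is discarded in favour of the submodel. The
fixed-effects core is an independent IRLS implementation, cross-checked
against `glm` in the tests.

**Conditional-inference forest.** Trees are grown on independent subsamples
drawn *without replacement*; at each node `mtry` candidate predictors are
scored by the permutation-test association framework (standardized linear
statistic for continuous predictors, chi-square for factors), and the
minimum-p predictor is split at the point (or binary level subset,
enumerated exhaustively up to 10 levels) maximizing the standardized
two-sample statistic. Predictions average leaf used-fractions; rows outside
a tree's subsample form its out-of-bag (OOB) set. Permutation importance is
the mean OOB error increase when one predictor's values are scrambled —
a measure that sees information expressed only through interactions.

A note on stopping: single conditional-inference *trees* conventionally
stop when the Bonferroni-adjusted p-value exceeds $\alpha = 0.05$
(`grow_tree()`'s default). Conditional-inference *forests* conventionally
grow unstopped trees (`alpha = 1`, nodes split while they hold at least
`min_node = 20` rows, children at least 7) and let ensemble averaging
regularize; `fit_forest()` follows the forest convention. In our
simulations significance-stopped 3% subsample trees average about six
leaves, too coarse to express a humped response, and the forest loses both
its cross-validation edge and its ability to recover nonlinear shapes;
unstopped trees restore both. Both conventions remain available through
`alpha`.

**Interaction-strength index.** For a pair of predictors: (1) each is cut
into 10 equal-width bins over its observed range and the model is predicted
on the $10 \times 10$ grid of bin midpoints, all other covariates held at
their means (categorical at the reference class); (2) the 100 predictions
are fitted by least squares with an additive two-factor model — one free
parameter per bin per variable, sum-to-zero identification, 20 effective
parameters (we adopt the sum-to-zero convention; with an intercept and
treatment contrasts the fitted values, hence the index, are identical);
(3) the index is the residual RMSE. For a $10\times10$ grid this equals the
classical two-way ANOVA interaction decomposition (double-centering), which
the tests assert to $10^{-10}$. Additive surfaces score exactly zero, so
the logistic model is evaluated on the *link* scale (where a model without
the pair's product term is exactly additive); the forest is evaluated on
the probability scale.

**Evaluation.** LOIO cross-validation holds out one animal at a time — the
animal, not the fix, is the independent unit — refits both frameworks, and
pools all out-of-fold scores into a single AUC per framework. AUC is the
Mann-Whitney probability with ties counted half, computed by midranks. The
DeLong test compares the two correlated AUCs through per-observation
placement values (also via midranks; an $O(n\log n)$ computation checked
against brute-force pair enumeration and an independent reference
implementation). We report $D$ (the z statistic) and a two-sided normal p;
the residual clustering of pooled scores by individual is not further
adjusted, a known limitation of pooling scores across individuals.

## The synthetic study conditions

The generator emulates a Great Basin mule-deer seasonal range at the scales
typical of published multi-year GPS-collar studies:

* **Landscape** — a 128 × 128 grid of 100 m cells (12.8 km square).
  Elevation is a smooth Gaussian random field (autocorrelation ~1.2 km)
  with availability mean 2,075 m and SD 250 m, clipped to 1,650–2,900 m —
  matching availability distributions typical of these ranges. Slope
  (degrees) and
  aspect derive from elevation by finite differences; water is two
  downhill-biased random-walk streams plus point springs, mildly favouring
  valley bottoms (a strong valley bias drives the elevation–water
  correlation above the 0.65 collinearity threshold and would knock
  elevation out of the design, which never happened in the real study);
  vegetation is five quantile-binned classes of an independent field with
  sagebrush as reference.
* **True selection surface** (logit scale) — a Gaussian hump in elevation
  (optimum 2,075 m, width 150 m, coefficient 2; the preferred band ~1,900–
  2,250 m straddles the availability mean, which is exactly what defeats a
  logit-linear term); a humped slope response (optimum 18°, width 10,
  coefficient 1, effectively a rise-then-plateau over the generated 0–25°
  terrain); a logistic threshold in distance to water (plateau of 2 logits
  within ~1 km, decaying over 150 m); a weak linear north-south aspect
  effect (0.3 per SD); vegetation-class effects (pinyon-juniper avoided at
  −1, and so on); and a slope-by-elevation interaction, coefficient 0.75 on
  availability-standardized scales, with each standardized covariate passed
  through `tanh` so the interaction saturates at terrain extremes — an
  unbounded product would make selection *rise again* at extreme
  elevations, contradicting the humped structure being emulated.
* **Telemetry** — 50 individuals × 250 daily fixes by default (a typical
  multi-year collaring effort: ~50 animals, ~200–300 fixes per animal per
  season). Each individual
  draws $b_i \sim N(0, 0.5^2)$ and its fixes are weighted multinomial
  samples over range cells with weight $\exp(\text{lp})$, jittered within
  the cell. Individuals use deterministic sub-streams of the seed, so
  adding animals never perturbs existing ones. An optional first-order
  movement mode (Gaussian kernel around the previous fix, re-weighted by
  selection) emulates the strong temporal autocorrelation of real collar
  data — the stated rationale for the 3% subsampling of the forest;
  the i.i.d. default keeps the sampling distribution exactly multinomial so
  the generator's own tests have closed-form oracles.

What the generator does *not* emulate: GPS fix error and dilution of
precision, migration-phase transitions, per-individual home ranges within
the population range (the random intercept shifts an individual's overall
use intensity, not *where* it goes — a softmax over cells is invariant to a
constant shift, so $\sigma_b$ is exercised directly in the mixed-model
recovery simulations rather than through the spatial pattern), and real
LANDFIRE vegetation classes. Passing tests therefore demonstrate that the
pipeline recovers known structure from data *with these statistical
properties*, not that any real population selects habitat this way.

## Design and numerical choices

* **Range delineation** — the population range is the 99.9% isopleth of a
  Gaussian KDE of all used points (bandwidth: Silverman's rule per axis,
  overridable), buffered by a configurable distance (1,500 m summer /
  1,000 m winter are the conventional values); availability is sampled
  uniformly at 1:1 within the buffered range, per season over the pooled
  population range. The isopleth accumulates cells in descending density
  order until the mass bound is met, so the bound is tight by construction.
* **Available-row grouping** — the mixed model needs a grouping for
  available rows; each individual receives exactly as many available rows
  as it has used rows, which simultaneously defines LOIO fold membership.
* **Covariate extraction** — nearest (containing) cell, keeping categorical
  extraction exact; aspect is emitted as $1+\cos\theta$ and $1+\sin\theta$
  (each in $[0,2]$, mean ~1 on varied terrain).
* **Collinearity screen** — greedy: while any pair exceeds $|r| = 0.65$,
  drop the member of the worst pair with the larger mean absolute
  correlation (ties broken by column order); constant columns are excluded
  from the screen with a warning but retained. Re-running on the retained
  set is a no-op.
* **Degenerate cases** — complete separation in the logistic fit is flagged
  with a warning, not an error; a single grouping level returns the
  fixed-effects fit with `sigma_b = NA`; vegetation classes absent from a
  CV training fold are collapsed to the reference class for that fold;
  factor levels never seen in forest training are routed by the
  majority-direction rule with a warning; `sigma_b` estimates below
  $10^{-4}$ are flagged as boundary fits.
* **Tolerances** — IRLS stops at score norm $<10^{-8}$ (cap 100
  iterations); interaction bins are equal-width (the grid is evaluated, not
  binned data, so empty bins cannot arise); PD grids use bin midpoints over
  the observed range.

## Problem sizes used in the checks

The full study scale (50 × 250 fixes, 500 trees at 3% subsampling, 50-fold
LOIO) runs end to end in minutes (`run_all(run_config())`), but repeating
it across ten seeds inside a routine test run would be wasteful. The
package's own checks therefore run the same pipeline at reduced sizes
chosen to preserve the statistics that matter: 15 individuals × 120 fixes
with 80-tree forests at 25% subsampling for the cross-validation
comparison (per-tree sample sizes match the full-scale 3% equivalent of
~750 rows), and 25 × 160 with 400 trees at 15% for the partial-dependence
and interaction analyses. The vignette states these as the package's
standard simulation sizes; all of them can be scaled back up through
`run_config()`.

## Known limitations

* The random intercept does not displace individuals spatially (see above),
  so the synthetic telemetry under-expresses between-animal habitat
  heterogeneity relative to real migratory herds.
* Partial dependence holds non-focal covariates at their means — in
  correlated terrain this evaluates the model partly outside the data
  cloud, attenuating recovered effect sizes (visible in the water-threshold
  analysis, where the forest recovers the breakpoint location exactly but
  compresses its amplitude).
* The DeLong test treats pooled out-of-fold scores as independent
  observations; with strongly autocorrelated telemetry its p-values are
  anti-conservative.
* The interaction index shares the partial-dependence extrapolation caveat
  and measures only bivariate structure.
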