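---
title: "Soil-augmented reaction-norm models: methods and design notes"
author: "soilnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-augmented reaction-norm models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilnorm)
```

## The problem

Advanced yield trials in a soybean breeding program test hundreds of
lines across environments (year-by-farm trials) that differ in, among
many other things, soil texture.  Genomic prediction lets the program
predict the yield of lines in environments where they were never grown
-- or never grown at all -- from a SNP panel and the phenotypes of
relatives.  Whereas weather is unknowable at planning time, soil texture
is a stable, known-in-advance environmental covariate.  This package
implements and evaluates a family of Bayesian multi-kernel GBLUP models
that exploit it.

## Models

With $y_{ij}$ the yield of line $i$ in environment $j$ (soil class
$k = k(j)$), the most complete model (M3) is

$$y_{ij} = \mu + E_j + S_k + L_i + g_i + gE_{ij} + gS_{ik} +
  \varepsilon_{ij},$$

where all terms are independent mean-zero Gaussians: environment
$E_j \sim N(0, \sigma^2_E)$, soil class $S_k \sim N(0, \sigma^2_S)$,
line $L_i \sim N(0, \sigma^2_L)$, genomic value
$g = \{g_i\} \sim N(0, G\sigma^2_g)$ with $G = X_cX_c'/p$ the
marker-derived relationship matrix, and residual
$\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon)$.  The interaction
terms are the reaction-norm kernels: at the record level,

$$gE \sim N\!\big(0,\ (Z_LGZ_L') \,\#\, (Z_EZ_E')\ \sigma^2_{gE}\big),
\qquad
gS \sim N\!\big(0,\ (Z_LGZ_L') \,\#\, (Z_SZ_S')\ \sigma^2_{gS}\big),$$

where $Z_L, Z_E, Z_S$ are record-to-level incidence matrices and $\#$
is the Hadamard (cell-by-cell) product.  Intuitively, the $gE$ kernel
correlates two records exactly when they share an environment, by the
genomic relationship of their lines; $gS$ does the same within a soil
class, which lets information travel between environments that sit on
the same soil.  Four nested models are exposed:

| model | terms |
|---|---|
| M1 | $E + L + G$ (main-effects GBLUP) |
| M2 | $E + L + G + G{\times}E$ (reaction norm) |
| M3 | $E + L + S + G + G{\times}E + G{\times}S$ |
| M4 | $E + L + S + G + G{\times}S$ |

All random-effect kernels are symmetric and positive semidefinite
(Hadamard products of PSD matrices are PSD by the Schur product
theorem); `check_kernel()` enforces symmetry to $10^{-10}$ and the
smallest eigenvalue to $\ge -10^{-8}$ of the largest.

### Marker coding

`genomic_relationship()` imputes missing 0/1/2 dosages with the marker
mean, centers each marker column, and by default scales columns to unit
variance before forming $G = X_cX_c'/p$, so the diagonal averages about
1 and variance components are on the phenotypic scale.  Both switches
are exposed (`center`, `scale`); the literal uncentered cross-product is
available because published analyses do not always state their coding
convention, and the convention shifts variance-component estimates
slightly.  Kernels are not trace-normalized by default
(`model_kernels(..., normalize = TRUE)` divides by the mean diagonal).

## Inference

`reaction_norm()` fits any of the four models by Gibbs sampling.  Each
effect vector is reparameterized through the eigendecomposition of its
record-level kernel, $K_t = \Gamma_t\Lambda_t\Gamma_t'$, as
$u_t = \Gamma_t\alpha_t$: because the columns of $\Gamma_t$ are
orthonormal, the coordinates of $\alpha_t$ have independent normal full
conditionals and one update costs two matrix-vector products.
Eigendecompositions are computed once per fit and reused every
iteration; eigenvalues below $10^{-8}$ of the largest are dropped
(rank truncation doubles as the numerical jitter guard for singular
kernels such as a rank-deficient $G$).

Variance components get conjugate scaled-inverse-chi-square priors.
Defaults: degrees of freedom 5 for every term and the residual; scales
derived so each model term's prior mode is an equal share of 50% of the
observed phenotypic variance and the residual prior mode is the
remaining 50%.  This weakly-informative default is the common choice
for this model class; all hyperparameters are exposed through
`prior_spec()`.  With few levels the prior is not innocuous -- a
3-level soil factor or a 20-level environment factor keeps a visible
prior pull (a few percentage points of share) that shows up in the
recovery experiments below.

Masked records (cross-validation test sets, or `NA` yields) are handled
by data augmentation: each iteration they are imputed from the current
linear predictor plus residual noise, so one code path serves the
full-data fit and all cross-validation schemes.  Predictions are
posterior means of the linear predictor.  The sampler is bit-reproducible
given `mcmc_control(seed = )`, and restores the caller's RNG state.

MCMC defaults are 12,000 iterations, 2,000 burn-in, thinning 5 --
appropriate for a production fit.  The package's own tests and the
acceptance script use shorter chains (600-6,000 iterations) on smaller
simulated problems (15-200 lines, 6-20 environments); these sizes were
chosen so the whole suite runs in minutes while every posterior summary
they assert is stable at the asserted tolerance.  Effective sample
sizes of the variance chains are reported per component
(`variance_components()`), not enforced.

As an independent check, `mme_oracle()` computes the closed-form best
linear predictor when all variances are fixed:
$\hat y_{test} = C_{test,train}(C_{train,train} +
\sigma^2_\varepsilon I)^{-1}(y_{train} - \bar y) + \bar y$ with
$C = \sum_t \sigma^2_t K_t$.  The test suite verifies that the Gibbs
sampler, run with variance sampling disabled, reproduces the oracle
within Monte-Carlo error on several toy configurations -- a strong
end-to-end check of the kernel algebra and the sampler's full
conditionals.

## Cross-validation schemes

`cv_partitions()` implements the four breeding scenarios: CV2 (records
to folds; incomplete trials), CV1 (lines to folds; new lines in known
environments), CV0 (leave one environment out; known lines in a new
environment) and CV00 (as CV0, with every record of the held-out
environment's lines also removed from training; new lines in a new
environment).  Folds are split as evenly as possible; per-replicate
seeds derive deterministically from the master seed.  CV00's test set
is the full CV0 test set -- the most literal reading of
"remove all phenotypic information of the testing genotypes".  The
no-leakage property (no test line has any training record) is asserted
exhaustively in the tests.  `run_cv()` refits the model per partition,
masking everything outside the training set.

## Evaluation metrics

* Per-environment Pearson correlation $r_j$ between predicted and
  observed, with sampling variance $V(r_j) = (1 - r_j^2)/(n_j - 2)$;
  environments with $n_j < 3$ or degenerate variance are skipped with a
  reason.
* Weighted mean correlation
  $r_w = \sum_j (r_j / V_j) \big/ \sum_j (1 / V_j)$.  Entries with
  $V_j = 0$ ($|r_j| = 1$, infinite weight) are excluded at this step;
  negative correlations are retained.
* Variance-share tables: each component over the sum of all components,
  times 100; the within-environment variant removes the environment
  term from numerator set and denominator.
* Percentile classification grids: predictions and observations are
  each cut at their own empirical 20/50/80 percentiles (type-7 linear
  interpolation; boundary values fall to the lower category, a
  documented and configurable tie-break) and the 4x4 conditional
  proportions of observed given predicted categories are tabulated.
  The (top, top) and (bottom, bottom) cells are the top-20% and
  bottom-20% classification successes; $R^2$ (OLS of observed on
  predicted, equal to the squared correlation) and MSE accompany the
  grid.
* `genotype_overall()` centers observed and predicted values on their
  environment means and averages per line, for the across-environment
  view of genotype merit.

## The simulator

`simulate_trials()` emulates the structure of the trial system the
models target: lines split into yearly cohorts; each year a set of
environments labeled silt loam / clay / fine sand across two farms;
incomplete line-by-environment incidence (`obs_rate`, default 0.9 --
the deposited real data are unbalanced but the exact rate is not
reported, so one realistic value was fixed once); optional cohort
carryover between years (default 0; the real overlap is unreported and
exposed as a free parameter).  Markers are independent binomial(2, q)
dosages.  Defaults (797 lines, 5 years, 2+2+1 environments per year,
~6k markers, grand mean 50, total variance 100 split as the fitted M3
decomposition of the real system) reproduce the scale of the emulated
program; analyses in the tests use smaller instances of the same
structure.

Phenotypes are assembled exactly from the generative model above;
interaction effects are drawn per environment (and per soil class) as
$\Gamma\sqrt{\Lambda}z$ from the eigendecomposition of $G$, which
induces exactly the Hadamard covariance.  The stored truth object
recombines to the phenotypes to $10^{-10}$.

**Variance targeting.**  With `scale_exact = TRUE` (default) every
sampled effect vector is centered and rescaled so its empirical
variance equals its configured component, and the draws are
orthogonalized against lower-order terms: environment effects are
centered within soil classes, $gE$ rows are centered within each soil's
environments, and $gS$ rows are centered across soils.  Without this,
the *realized* variance of a 20-environment or 3-soil-class draw
deviates from its nominal value by far more than the recovery
tolerances of interest (the sampling SD of a 3-draw variance is ~80%),
and random overlap between, e.g., soil-class means of the environment
effects and the soil main effect shifts shares by several percentage
points.  Variance targeting makes the nominal shares the realized
estimands, which is what a recovery experiment should test;
`scale_exact = FALSE` gives the literal i.i.d. draws for moment-level
checks.

**What the simulator does not emulate.**  Lines are unrelated (no
bi-parental family structure, no linkage disequilibrium), markers are
independent, there are no spatial trends and no replicate-level block
effects (the models operate on entry means, one record per
line-by-environment).  The absence of family structure matters: with
unrelated lines the genomic relationship carries almost no information
about an untested line, so CV1/CV00 predictive abilities on synthetic
data are much lower than on real breeding data, where full-sibs anchor
the prediction.  Passing tests therefore demonstrate correctness of the
machinery and the qualitative scheme ordering, not the absolute
accuracies attainable on real programs.

## Recovery and ordering experiments

Fitting M3 to simulated trials (200 lines, 20 environments, 3 soils,
shares E=45, L=2, S=12, G=4, GxE=11, GxS=10, R=16%) recovers every
across-environment share within 5 percentage points averaged over
3 seeds.  The residual biases are understood: the equal-share prior
pulls the 3-level soil share up and the 20-level environment share down
by 3-4 points each.  On genetics-rich simulated trials the weighted
mean correlations order as observed in practice: CV2 above CV1, CV0
above CV00, and CV2 above CV00 paired over seeds.

## Degenerate inputs and numerical choices

* Constant phenotypes: prior scales are floored at $10^{-8}$ so the
  sampler stays defined; all variance components collapse toward zero
  and predictions return the constant.  (Their *ratios* then follow the
  prior and term ranks -- no likelihood information orders them -- so
  variance shares are not meaningful on such data.)
* Monomorphic markers are dropped when scaling; an all-monomorphic
  panel is an error.
* `mme_oracle()` retries a failed solve with $10^{-8}$ diagonal jitter.
* Duplicate (line, environment) phenotype rows are rejected by default
  or averaged under `duplicates = "mean"` (entry means of replicated
  field plots; the models index one record per line-by-environment).
* Environment identity is taken verbatim from the `env` column --
  distinct trials on the same farm and soil are distinct environments.
  Soil is an open categorical set, not hard-coded to three classes.

## Known limitations

* No REML/frequentist fitter; no multi-trait models; residual variance
  is homoscedastic across environments.
* No VCF/PLINK parsing -- markers arrive as 0/1/2 CSV.
* The percentile-grid "BLUP-centered" display variant is not
  implemented; centering uses environment means of the plotted values.
* Weather-based environmental covariates are out of scope; soil texture
  is the only environmental descriptor beyond environment identity.
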