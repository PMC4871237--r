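---
title: "Building fractional polynomial models with multiply imputed covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building fractional polynomial models with multiply imputed covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmi)
```

## The model

A fractional polynomial (FP) of dimension $D$ lets a strictly positive
continuous covariate $x$ enter a regression model through the linear
predictor

$$\beta_0 + \sum_{d=1}^{D} \beta_d\, x^{p_d},$$

with exponents $p_d$ drawn from the conventional candidate set
$S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, the convention $x^0 = \log x$,
and a repeated pair $(p, p)$ contributing $x^p$ and $x^p \log x$.  FP1
functions are monotone; FP2 functions accommodate J- and U-shapes.  The
family applies unchanged to Gaussian and logistic regression (`fp_fit()`
supports both).  Covariates with non-positive values are first shifted so
that the smallest value equals the smallest increment between any two
distinct values; the shift is recorded by the data containers and all
selected exponents refer to the shifted variable.

### The function selection procedure

With complete data, model complexity for one covariate is chosen by a
closed sequence of likelihood-ratio tests against the best-fitting
FP$D_{\max}$ model (`fsp_complete()`): first the null model (the
*inclusion* test, at level $\alpha_{\mathrm{incl}}$), then the linear
model, then FP1, each at level $\alpha$.  The selected model is the
simplest whose test is not significant.  Degrees of freedom count one per
coefficient and one per estimated exponent, so FP1-vs-null is referred to
$\chi^2_2$, FP2-vs-FP1 to $\chi^2_2$, and FP$m$-vs-linear to
$\chi^2_{2m-1}$ (`test_df()`).  Because each exponent is in truth chosen
from a small discrete set, the one-df-per-exponent convention is
generous, and the inclusion test is mildly conservative: in our null
simulations its rejection rate at nominal 0.1 is about 0.06.  Both test
levels default to 0.1, a conventional choice for FP model building.

Multivariable (MFP) model building cycles this procedure over the
covariates, conditioning each test on the currently selected forms of
the others, until a full cycle changes nothing (`mfp_mi()`; the cap is
`max_cycles = 5`, and in the simulation designs below convergence almost
always occurs within two cycles).  Covariates are visited in ascending
order of the p-value of their coefficient in an initial all-linear
pooled fit; the order is deterministic but, like all MFP variants, the
result can in principle depend on it.

## Imputation that does not prejudge the exponent

When $x$ is partially observed and the eventual FP form unknown, an
imputation model built around any single transformation would be
incompatible with most of the candidate analysis models.  The package's
imputation (`mi_impute()`) instead draws the exponent anew for every
imputation via the approximate Bayesian bootstrap (ABB):

1. resample the complete cases with Dirichlet$(1, \dots, 1)$-weighted
   multinomial probabilities (`abb_resample()`);
2. on the resample, regress $x^p$ on $y$ and the other covariates for
   every $p$ on a fine grid ($-2$ to $3$ in steps of $0.2$, 26 values);
3. pick $p^\ast$ maximising $\log L + J$, where
   $J = \sum_i \log |d(x_i^p)/dx_i|$ is the Jacobian making
   log-likelihoods comparable across transformations
   (`jacobian_adjustment()`); as the maximiser from a bootstrap
   resample, $p^\ast$ is a draw from the approximate posterior of $p$;
4. on the original complete cases, fit a Bayesian linear regression of
   $x^{p^\ast}$ on $y$ and the other covariates — residual variance from
   its scaled inverse-$\chi^2$ posterior, coefficients from their
   conditional normal;
5. impute the missing $x^{p^\ast}$ from that posterior predictive draw,
   keeping imputations positive either by predictive mean matching
   (default; a random donor among the `donor_k = 3` observed cases with
   the closest predicted mean, so every imputed value is an observed
   value) or by a truncated-normal draw bounded at the transformed value
   of half the smallest observed $x$;
6. back-transform by the $p^\ast$-th root ($\exp$ for $p^\ast = 0$).

Step 4 deliberately fits on the original complete cases rather than the
ABB resample: the resample's only job is to propagate uncertainty in
$p$, while parameter uncertainty in the imputation regression is carried
by the posterior draw.  Incomplete binary covariates are imputed by
Bayesian logistic regression.  With two or more incomplete covariates
the algorithm runs as chained equations, each covariate conditioning on
the current values of the others, for `fcs_cycles = 10` cycles; a single
incomplete covariate needs only one pass because its conditional model
never changes.  Chains start from random draws from each covariate's
observed margin.  Collinear predictor columns encountered during the
exponent draw are dropped with a warning rather than failing the
replicate.

The drawn exponent's behaviour is worth noting.  Under a strong signal
(correlation 0.7, $n = 300$) the $p^\ast$ distribution over fresh
datasets is centred on the generating exponent, with about 90% of draws
within one grid step.  Under independence of $x$ and $y$ the draw does
*not* flatten to uniformity: the regression of $x^p$ on $y$ retains the
marginal-normality information in the Jacobian-adjusted likelihood, so
$p^\ast$ still concentrates on whichever power best normalises $x$.
Only the analysis-direction profile (of $y$ on $x^p$) is flat in that
case.

## Estimation and testing on multiply imputed data

Multiple imputation yields $M$ completed datasets; estimates are pooled
by Rubin's rules (`rubin_pool()`: mean, within-variance $W$, between-
variance $B$, total $T = W + (1 + 1/M)B$).  Likelihood-ratio statistics
are not directly meaningful across imputations, so the package offers
two coherent routes through the selection ladder (`fsp_mi()`):

* **Stacking.**  The $M$ datasets are treated as one of $n \times M$
  rows.  For estimating the exponent, candidate models of equal
  complexity may be ranked by the unweighted stacked log-likelihood —
  the ordering is invariant to any common positive weighting
  (`estimate_p_stacked_ll()`).  For *testing*, every observation is
  weighted by $w_c = (1 - f_c)/M$, where $f_c$ is the fraction missing
  of the covariate under scrutiny, approximating the fraction of lost
  information; the test statistic is $2 w_c (\ell_1 - \ell_0)$ on the
  stacked fits.  With no missing data $w_c = 1/M$ cancels the $M$-fold
  duplication exactly, so the procedure collapses algebraically to the
  complete-data likelihood-ratio ladder.

* **Wald / delta-Wald.**  For each candidate exponent the FP coefficient
  block is pooled by Rubin's rules and the Wald statistic
  $\bar{q}^{\mathsf T} T^{-1} \bar{q}$ computed; the estimate maximises
  this statistic (`estimate_p_wald()`).  Tests against the null model
  use the pooled Wald statistic directly; between non-nested classes
  (FP1 versus linear) the difference of the two models' Wald statistics
  against the common null serves as the statistic (`delta_wald()`).  A
  negative difference is possible; it is never significant and is
  flagged.  Reference distributions and dfs are identical to the
  complete-data ladder.

Both routes always compute the full test trail; the closed-test rule
determines `selected`.  The Wald route agrees with the likelihood-ratio
decision asymptotically, and exactly reproduces a complete-data *Wald*
ladder when nothing is missing, but a borderline call can differ from
the LRT ladder in finite samples — the stacked route is the one with an
exact degenerate-data identity.

## The simulation harness

Two study designs are built in, and their generators define the study
conditions rather than exposing tuning dials.

**Exponent estimation** (`run_estimation_study()`): $(y, x^p)$ bivariate
normal with means $(0, 3)$, unit variances and correlation 0.7 at
$n = 300$ — strong enough that the true analysis model has essentially
100% power — with $p \in \{0, 0.5, 1, 2\}$; 40% of $x$ set missing at
random (missingness probability 0.2 where $y \le 0$, 0.6 where
$y > 0$).  Rows whose $x^p$ is non-positive are redrawn (probability
about 0.0013 per row, so the distortion is negligible).  The study
tabulates the exponent selected by complete-data log-likelihood,
complete-records log-likelihood, stacked log-likelihood and pooled Wald
over the fine grid.

**Model selection** (`run_selection_study()`): two covariates with
$(x_1^{-0.5}, x_2)$ bivariate normal, means $(0.6, 3)$, SDs
$(0.2, 1)$, correlation 0 or 0.5, and
$y = \beta_0 + \beta_1 x_1^{-0.5} + \beta_2 x_2 + \varepsilon$ with
$\sigma_y = 1$ (the residual SD and intercept are not identified
separately from the effect calibration, so both are fixed: location
does not move any test statistic).  The off-diagonal of the covariate
model is stated in the source design as "$\sigma_1\sigma_2$ set to 0 or
0.5", which cannot be a covariance (it would imply correlation 2.5);
it is implemented as the correlation.  $\beta_2$ — and $\beta_1$ for
power scenarios — are calibrated by simulation with common random
numbers so the corresponding complete-data test has 90% power at
$\alpha = 0.1$ (`calibrate_effect()`, bisection to within 0.01 of the
target).  Missingness strikes $x_1$, $x_2$ or both: MCAR with
observation probability 0.7, or MAR with
$\mathrm{logit}\, P(R = 1 \mid y) = \omega_0 + \omega_1 y$,
$\omega_1 < 0$, calibrated by nested quadrature root-finding so that
70% of values are observed and the AUC of missingness against $y$ is
0.65 (`calibrate_mar_params()`, tolerance 0.005).  Each replicate is
imputed ($M$ imputations, PMM positivity, fine exponent grid) and the
MFP algorithm run for both covariates (maximum dimension FP1, both
test levels 0.1) four ways: complete data, complete records, stacking,
delta-Wald.  Rejection of the FP1-vs-null and FP1-vs-linear tests for
$x_1$ is recorded *marginally* on every replicate — the
FP1-vs-linear type-I error would otherwise be confounded with the
inclusion test's outcome — and aggregated with binomial Monte-Carlo
standard errors.

### Numerical choices and problem sizes

Replicate-level seeds are spawned from the master seed, so every runner
is deterministic end to end.  Ties in exponent profiling go to the first
candidate in ascending grid order.  Gaussian log-likelihoods use the ML
variance (comparability of likelihood ratios); coefficient covariances
use the unbiased residual variance.  Logistic fits use IRLS with a
deviance tolerance of $10^{-8}$ and at most 100 iterations;
non-convergence and separation are errors, never silent results.  The
package's own test suite exercises the selection studies at $n = 200$
with 500 replicates and $M = 5$, and the estimation machinery at
$n = 300$ — sizes chosen to give Monte-Carlo standard errors around
0.013 on a rejection rate while keeping a full run comfortably
interactive; the full-scale designs ($M = 10$, thousands of
replicates) are available by configuration.

### What the generators do and do not emulate

The generators reproduce joint-normal covariate/outcome structure,
exactly-known missingness mechanisms, and effect sizes calibrated to
known power.  Real epidemiological data depart from this in ways the
simulations deliberately do not model: skewed and heteroscedastic
outcomes, measurement error, missingness depending on unobserved values
(MNAR), many correlated covariates with non-monotone missingness
patterns, and imputation-model misspecification beyond the mild
covariate-scale kind.  Passing tests therefore certify the machinery
and its calibration under the stated conditions, not performance on any
particular real dataset.  Two behaviours observed at the reduced scale
deserve note: the inclusion test's conservatism (above), and mild
inflation of the $x_1$ type-I error (up to roughly 0.15–0.17 at
$n = 200$, $M = 5$) when a strong confounder correlated with $x_1$ is
imputed — the price of imputing a covariate whose own association with
the remaining covariates is modelled only linearly.

## Known limitations

The ABB exponent draw applies to FP1 imputation only; imputation
compatible with FP2 analysis models (e.g. by fitting all exponent
pairs) is out of scope, as are rejection-sampling (substantive-model
compatible) imputation, missing outcomes, MNAR mechanisms, survival
models, and FP dimensions above 2.  The final pooled model is reported
conditional on the selected exponents, as is conventional for FP
models; no second, form-restricted imputation pass is attempted.

## A worked example

```{r, eval = FALSE}
set.seed(1)
cfg <- study1_config(true_p = 0.5, reps = 1)
dat <- gen_study1(cfg)
inc <- apply_mar_study1(dat, cfg)
mi <- mi_impute(inc, mi_config(M = 10, seed = 2))
fsp_mi(mi, "x", Dmax = 1, method = "deltawald")
```
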