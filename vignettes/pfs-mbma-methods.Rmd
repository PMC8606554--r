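---
title: "Model-based meta-analysis of progression-free survival: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based meta-analysis of progression-free survival: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmbma)
```

## The problem

Published randomized trials of PARP-inhibitor maintenance therapy in
recurrent ovarian cancer report progression-free survival (PFS) as
Kaplan-Meier curves, not individual patient data. Model-based meta-analysis
(MBMA) pools such aggregate evidence by fitting a parametric survival model
to the digitized arm-level survival fractions, with a study-level random
effect absorbing between-trial heterogeneity and a covariate model
quantifying design differences (monotherapy versus combination therapy,
biomarker strata, drugs). `survmbma` implements that workflow end to end:
domain containers and CSV I/O for the arm-level table, four parametric
hazard families, marginal-likelihood estimation, stepwise covariate
selection, the standard diagnostics (goodness-of-fit residuals, visual
predictive check, bootstrap, leave-open-label-out sensitivity), and
Monte-Carlo scenario simulation of median PFS.

Because the digitized dataset behind the source analysis is not deposited,
the package ships a synthetic-corpus generator whose defaults reproduce the
published design (8 studies, 12 arms, 1,169 patients with the reported
drug, biomarker, therapy-type, partner and platinum margins) and the
published final-model parameters. Every pipeline stage is exercised against
corpora from this generator.

## Model

### Hazard families

Four instantaneous-hazard models are supported, each with a closed-form
survival function $S(t) = \exp(-\int_0^t h(u)\,du)$:

| family | $h(t)$ | parameters |
|---|---|---|
| exponential | $\lambda_0$ | $\lambda_0 > 0$ |
| gompertz | $\lambda_0 e^{\beta t}$ | $\lambda_0 > 0$, $\beta$ |
| weibull_form | $\lambda_0 e^{\beta \ln t} = \lambda_0 t^\beta$ | $\lambda_0 > 0$, $\beta > -1$ |
| lognormal | $f(t)/S(t)$ of a log-normal time distribution | $\mu$ (ln months), $\sigma > 0$ |

The `weibull_form` family is kept in its printed parameterization — a
Weibull hazard with shape $\beta + 1$ — rather than re-parameterized to the
standard (shape, scale) pair. The Gompertz cumulative hazard
$\lambda_0(e^{\beta t} - 1)/\beta$ has a removable singularity at
$\beta = 0$; `expm1` and a two-term series below $|\beta| < 10^{-8}$ handle
the limit, so both shape families collapse exactly onto the exponential at
$\beta = 0$. For the log-normal family, $\mu$ is the location of
$\ln(\text{time})$ — the median survival time is $e^\mu$, and $\sigma$ is
the log-time scale; the hazard evaluates the density/upper-tail ratio on
the log scale through `pnorm(..., lower.tail = FALSE, log.p = TRUE)` so
late-time hazards do not cancel catastrophically.

### Hierarchy and residuals

Study $i$ carries a random-effect vector $\eta_i$ acting multiplicatively
on the variability-bearing parameters,

$$P_i = P_{pop} \cdot e^{\eta_i}, \qquad \eta_i \sim N(0, \omega^2),$$

applied to both $\mu$ and $\sigma$ for the log-normal family (the final
parameter table of the source analysis reports separate between-study terms
for both) and to $\lambda_0$ for the other families. The covariance between
the two effects is fixed at zero, since no covariance is reported.
$P_{pop}$ is the typical value scaled by the covariate engine: categorical
covariates multiply by $(1 + \theta)$ off the reference level, continuous
covariates by $e^{(x - \tilde{x})\theta}$ centred at the n-weighted corpus
median $\tilde{x}$.

The observed fraction at time $j$ of study $i$ follows the combined
residual model

$$\mathrm{Obs}_{j,i} = \mathrm{Pred}_{j,i}\,(1 + SE_{j,i}\,\varepsilon^{(1)}_{j,i}) + SE_{j,i}\,\varepsilon^{(2)}_{j,i},$$

with $\varepsilon^{(1)} \sim N(0, \varepsilon_{prop}^2)$,
$\varepsilon^{(2)} \sim N(0, \varepsilon_{add}^2)$ and
$SE = \sqrt{p(1-p)/N}$ the binomial standard error of the observed
fraction, so the residual variance of a point is
$V_j = SE_j^2(\mathrm{Pred}_j^2 \varepsilon_{prop}^2 + \varepsilon_{add}^2)$.
The published residual rows are interpreted as standard deviations, not
variances: as SDs, the between-study terms (0.159 on $\mu$) imply a
plausible ~16% coefficient of variation, whereas as variances they would
imply between-study spreads incompatible with the published scenario bands.

Two numerical choices around the residual model matter in practice:

* **Boundary-censored fractions.** A fraction recorded exactly at 0 or 1
  (the generator clips noisy values into $[0,1]$) has a degenerate binomial
  SE and would otherwise get near-infinite weight. Such points enter the
  likelihood as censored: the latent pre-clipping value lies beyond the
  bound, with probability computed from the model prediction and the
  prediction-based SE. Without this treatment the scale parameter is biased
  about $-11\%$ and the proportional residual SD collapses to zero.
* **Interior weighting SE.** For interior points the weighting SE follows
  the printed formula (observed fraction), with the fraction clamped to
  $[0.5/n,\, 1 - 0.5/n]$ — a continuity correction that never triggers for
  interior data but guards freshly read corpora. The `se` column stored in
  the corpus is always the literal binomial SE of the observed fraction.

### Marginal likelihood

The marginal likelihood integrates each study's $\eta_i$ out of the joint
density. The integral is approximated by a Laplace expansion at the
conditional mode — the open-source analogue of the first-order conditional
estimation used by the proprietary tool named in the source analysis. The
conditional mode is found by a damped Newton search started from
$\eta = 0$ with an analytic gradient; steps are proposed with a
Gauss-Newton curvature (always positive definite) and the Laplace
determinant uses an exact finite-difference Hessian of the gradient at the
mode. Starting every inner solve from the same point keeps the marginal
objective a *pure function* of the outer parameters; warm-starting the
inner solver from cached modes made the objective path-dependent at the
$10^{-6}$ level, which is enough to trip a quasi-Newton outer optimizer
into false convergence. The test suite bounds the Laplace error against
9-node adaptive Gauss-Hermite quadrature (agreement well inside 0.5 OFV
units on small corpora; the acceptance suite enforces that bound).

The outer problem minimizes the objective function value
(OFV, $-2\log$ marginal likelihood) over transformed parameters — log scale
for $\sigma$, $\omega$ and $\varepsilon$ components — with `nlminb` at a
relative tolerance of $10^{-8}$, from a data-driven start (interpolated
median-crossing times) and up to two further seeded, jittered restarts if
the first start fails; the restart budget is spent only on failure, which
keeps routine fits at a single optimization. When `nlminb` reports "false
convergence" — which a profile that is flat in $\varepsilon_{prop}$
regularly provokes — the optimum is re-checked by restarting from the
returned point; an optimum stable under restart (improvement
$< 10^{-3}$ OFV) is reported as converged. Relative standard errors come
from a central-difference Hessian of the OFV, delta-transformed to the
natural scale, mirroring the "estimate (SE%)" layout of the published
parameter table.

### Covariate selection

Forward inclusion requires an OFV drop greater than 2.71 ($p < 0.1$, 1 df);
backward elimination removes any covariate whose deletion fails to raise
the OFV by more than 3.84 ($p < 0.05$), worst first, iterating to
stability. Near-ties among forward candidates (within $10^{-6}$) resolve by
declaration order, so runs are deterministic. Covariates are tested on
$\mu$ by default, matching the final published model; multi-level
categorical covariates get one $\theta$ per non-reference level and are
tested jointly against the same scalar thresholds, since the source states
scalar cut-offs without a degrees-of-freedom adjustment. Continuous
candidates with blanks are imputed with the n-weighted median; imputation
always proceeds, while a patient-weighted missing share above 30% only
removes the covariate from candidacy (the published procedure imputes all
arms but declines to *test* poorly observed covariates). Candidate fits are
warm-started from the current model and cached by covariate-set signature,
so the backward test of a one-covariate model reuses the base fit.

### Diagnostics

`gof_tables()` reports PRED ($\eta = 0$), IPRED ($\eta$ at its empirical
Bayes estimate) and CWRES from the standard first-order linearization
around the EBE, with the within-study covariance
$G\,\Omega\,G^\top + \mathrm{diag}(V)$ decorrelated by its symmetric
inverse square root. `vpc()` simulates full corpus replicates (new study
effects, new residuals with each observation's weighting SE) and reports
the 2.5/50/97.5 percentile band *per design point* across replicates —
with a single replicate the band collapses onto it — plus the share of
observations inside their 95% band; percentiles use untruncated simulated
values, while a $[0,1]$-truncated copy is provided for plotting.
`bootstrap_model()` resamples *studies* with replacement (the study is the
unit carrying $\eta$, so arm-level resampling would break the correlation
structure), refits warm-started replicates, and summarizes converged
replicates by medians and percentile intervals. `sensitivity_refit()`
drops arms flagged as open-label (`blinded = FALSE`) and refits.

### Scenario simulation

`arm_parameters()` summarizes each arm by its covariate-adjusted typical
location parameter times the study's EBE multiplier, with a delta-method
standard error from the EBE conditional variance. This is one concrete
reading of "the model parameters of each arm" — the source does not define
the summary, and this choice is the only one in which arms within a
scenario differ at all; it also explains why simulated scenario medians
need not equal $e^{\mu_{pop}}$. `random_effects_pool()` performs
DerSimonian-Laird random-effects pooling (delegated to `metafor`, the
field-standard implementation; the hand-computed DL formula serves as the
independent oracle in the tests) with 90% z-intervals. The interval level
is exposed because the source labels the same intervals 90% in the methods
and 95% in the results table. `simulate_scenario()` draws the location
parameter from its pooled normal distribution 10,000 times, holds $\sigma$
at its population estimate (the final covariate model acts on $\mu$ alone),
and summarizes per-time survival and median PFS by the median and the
equal-tailed 90% band; log-normal medians use the closed form $e^{\mu}$,
other families solve $S(t) = \tfrac12$ by bracketed root-finding.

## The synthetic generator

`parp_design()` returns the default generating truth: the published
final-model parameters over a deterministic 12-arm allocation that reaches
the published margins exactly (drug totals 501/302/366, biomarker totals
669/100/400, therapy split 1,077/92 with partners 43 cediranib /
28 chemotherapy / 21 bevacizumab, platinum split 1,105/64, four of eight
studies open-label). The published drug-by-biomarker cell counts are
internally inconsistent with the drug totals, so the allocation honors the
margins and lets the cells fall where the deterministic split puts them.
The observation grid is 3-36 months at 3-month spacing — the extent of
typical published Kaplan-Meier figures — truncated where the noiseless
prediction falls below 2% survival (at least the three earliest points are
always kept); the grid spacing per digitized curve is not stated in the
source, so it is a generator parameter rather than a fixed constant.
`generate_corpus()` draws study effects, applies the covariate engine,
computes the prediction-based SE, adds the combined residual, clips to
$[0,1]$, and stores every latent draw in a `truth_record` attribute so
calibration tests can check the pre-clipping residual model directly.

What the generator deliberately does *not* emulate: digitization error
beyond the stated residual model, censoring-driven drift of the effective
at-risk population (the binomial SE uses the enrolled arm size at every
time), within-arm autocorrelation of digitized points along a curve, and
reporting artifacts such as number-at-risk tables. Passing recovery tests
on these corpora therefore demonstrates internal consistency of the
estimator with the assumed data-generating process, not robustness to real
digitization pipelines.

## Problem sizes and reproducibility

All stochastic routines take an integer seed and restore the caller's RNG
state, so identical calls are bit-identical. The shipped experiments use:
20 replicate corpora for parameter recovery, 10 for family discrimination,
20 for selection calibration, 1,000 VPC replicates and 10,000 Monte-Carlo
scenario draws in the analysis scripts (200 bootstrap replicates there,
scaled down from the published 1,000), and smaller sizes in the unit suite
where only the property, not the precision, is at stake.

## Known limitations

* The proportional residual SD $\varepsilon_{prop}$ is barely identified
  at the default study conditions: with the default values its share of
  the residual variance is at most
  $0.429^2/(0.429^2 + 1.241^2) \approx 11\%$, the OFV profile in it is
  nearly flat, and the MLE piles at the zero boundary in a large share of
  replicate fits — the recovery experiment in the acceptance suite shows
  its replicate median far below the generating value while all other
  parameters recover. Point estimates of this component should be read
  with corresponding caution.
* Study-level percentile bootstrap intervals can undercover when only a
  handful of studies are resampled; with eight studies the bootstrap is a
  robustness probe, not an exact interval method.
* The Laplace approximation replaces the proprietary FOCE linearization;
  the quadrature oracle bounds the difference on small corpora but exact
  numerical equality with the original tool is not expected.
* Scenario medians summarize the fitted synthetic corpus; reproducing the
  source's scenario table would require the undeposited digitized data.
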