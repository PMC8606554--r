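# survmbma

Model-based meta-analysis (MBMA) of progression-free survival (PFS) from
aggregate Kaplan-Meier data, built around the published pharmacodynamic
meta-analysis of PARP-inhibitor maintenance therapy in recurrent ovarian
cancer.

Randomized maintenance-therapy trials report PFS as Kaplan-Meier curves.
When only those curves are available, the evidence across trials can still
be pooled by fitting a parametric survival model directly to the digitized
arm-level survival fractions. `survmbma` implements that analysis for
biostatisticians and pharmacometricians:

* **Model.** Four parametric hazard families (exponential, Gompertz,
  Weibull-form `h(t) = λ0·t^β`, log-normal), with survival
  `S(t) = exp(−∫ h)` in closed form. Study-level random effects act
  multiplicatively, `P_i = P_pop·e^η`, `η ~ N(0, ω²)`, on μ and σ of the
  log-normal family; covariates scale the typical value
  (`P_pop = P_typ·(1 + θ)` for categorical, `P_typ·e^{(x−x̃)θ}`
  for continuous). Observed fractions carry a combined residual weighted by
  their binomial standard error `SE = √(p(1−p)/N)`:
  `Obs = Pred·(1 + SE·ε₁) + SE·ε₂`.
* **Estimation.** Laplace-approximated marginal likelihood (the open
  analogue of first-order conditional estimation), minimized as an
  objective function value (OFV = −2 log L); relative standard errors from
  the OFV Hessian; empirical Bayes study effects.
* **Covariate screening.** Forward inclusion at ΔOFV > 2.71 (p < 0.1),
  backward elimination at ΔOFV > 3.84 (p < 0.05), with n-weighted median
  imputation and a 30% missingness candidacy rule.
* **Evaluation.** Goodness-of-fit tables (PRED/IPRED/CWRES), visual
  predictive check with percentile bands, study-level nonparametric
  bootstrap, open-label sensitivity refit.
* **Simulation.** DerSimonian-Laird random-effects pooling of arm-level
  parameters per scenario, then 10,000-draw Monte Carlo of median PFS with
  a 90% band.
* **Synthetic corpus.** The digitized dataset behind the source analysis is
  not deposited, so `parp_design()` + `generate_corpus()` reproduce its
  design exactly — 8 studies, 12 arms, 1,169 patients with the published
  drug (501/302/366), biomarker (669/100/400), therapy (1,077/92) and
  platinum (1,105/64) margins — at the published final-model parameters
  (μ = 2.96, σ = 0.999, monotherapy effect −0.215 on μ, ω = 0.159/0.142,
  ε = 0.429/1.241).

## Worked example

```r
library(survmbma)

corpus <- generate_corpus(parp_design(), seed = 1)
corpus
#> <mbma_corpus> 8 studies, 12 arms, 142 observations, 1169 patients

model <- mbma_model("lognormal", list(
  covariate_effect("therapy_type", target = "mu", kind = "categorical",
                   reference = "combination")))
fit <- fit_mbma(corpus, model, seed = 1)
fit
#> <mbma_fit> family = lognormal (converged)
#>   OFV: -378.638 over 8 studies / 142 observations
#>   Parameter  Estimate (SE%)
#>   mu               3.066 (5.3)
#>   sigma           0.9923 (6.5)
#>   therapy_type   -0.2439 (22.2)
#>   omega_mu        0.1067 (19.2)
#>   omega_sigma     0.1599 (19.6)
#>   eps_prop        0.0108 (24.4)
#>   eps_add          1.211 (6.1)
```

The fit recovers the generating values on this corpus: location μ ≈ 3.07
(truth 2.96, so a typical combination-therapy median PFS of
`exp(3.07) ≈ 21` months), a monotherapy scaling factor of −0.24 (truth
−0.215, i.e. monotherapy shortens the log-median by ~24%), and
between-study SDs of ~0.11/0.16. The proportional residual SD is barely
identified at these study sizes (see the methods vignette) — its relative
SE is the largest in the table, as in the source analysis.

Pool the monotherapy arms and simulate their PFS:

```r
ap <- arm_parameters(fit, corpus)
pool <- random_effects_pool(ap, list(therapy_type = "monotherapy"))
pool
#> <mbma_pool> [therapy_type=monotherapy] k=9 pooled=2.3260
#>             (90% CI 2.1920-2.4599) tau2=0.05818

simulate_scenario(pool, sigma = fit$theta[["sigma"]], n_rep = 10000,
                  seed = 3)
#> <scenario_summary> [therapy_type=monotherapy] median PFS 10.23 months
#>                    (90% CI 8.93-11.70), 10000 reps
```

A pooled monotherapy location of 2.33 corresponds to a median PFS of
`exp(2.33) ≈ 10.2` months; the Monte-Carlo band propagates the pooling
uncertainty.

The `analysis/` directory runs the full workflow as numbered scripts
(`01_simulate.R` … `05_scenarios.R`), writing tables under `results/`:
corpus and margins, hazard-family OFV comparison, final parameter table,
stepwise-selection trace, GOF/VPC/bootstrap/sensitivity outputs, and the
per-scenario median-PFS summary.

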