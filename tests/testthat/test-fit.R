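test_that("residual_se is the binomial standard error", {
  expect_equal(residual_se(0.5, 100), 0.05)
  expect_equal(residual_se(1.0, 50), 0)
  expect_equal(residual_se(0.9, 90), sqrt(0.09 / 90))
  expect_equal(round(residual_se(0.9, 90), 7), 0.0316228)
  expect_error(residual_se(0.5, 0), "n must be >= 1")
  expect_error(residual_se(1.2, 10), "\\[0, 1\\]")
})

test_that("arm_prediction applies covariates and the study multiplier", {
  fit <- list(family = "lognormal",
              theta = c(mu = 2.96, sigma = 0.999),
              effects = list(covariate_effect(
                "therapy_type", target = "mu", kind = "categorical",
                theta = c(monotherapy = -0.215),
                reference = "combination")))
  tt <- c(3, 9, 18, 30)
  hp <- hazard_params("lognormal", mu = 2.96, sigma = 0.999)
  # eta = 0, reference level: the population survival curve
  expect_equal(arm_prediction(fit, list(therapy_type = "combination"), tt),
               surv_prob(hp, tt))
  # monotherapy scales mu by (1 - 0.215)
  hp_m <- hazard_params("lognormal", mu = 2.3236, sigma = 0.999)
  expect_equal(arm_prediction(fit, list(therapy_type = "monotherapy"), tt),
               surv_prob(hp_m, tt), tolerance = 1e-12)
  # multiplicative eta shifts the individual median to 1.1^... scale:
  # mu_i = 1.1 * mu, so the arm median is exp(2.96 * 1.1)
  pr <- arm_prediction(fit, list(therapy_type = "combination"),
                       exp(2.96 * 1.1), eta = c(mu = log(1.1)))
  expect_equal(pr, 0.5, tolerance = 1e-12)
  # output is monotone non-increasing
  expect_true(all(diff(arm_prediction(
    fit, list(therapy_type = "monotherapy"), seq(1, 40))) <= 0))
  expect_error(arm_prediction(fit, list(therapy_type = "monotherapy"), 0),
               "times")
})

test_that("marginal OFV with omega = 0 equals the closed-form Gaussian -2LL", {
  co <- random_corpus(5)
  # keep fractions off the boundaries so no censoring terms appear
  stopifnot(all(co$obs$obs_fraction > 0 & co$obs$obs_fraction < 1))
  mod <- mbma_model("lognormal")
  params <- list(fixed = list(mu = 2.5, sigma = 1.1),
                 omega = c(mu = 0, sigma = 0),
                 eps = c(prop = 0.4, add = 1.2))
  got <- marginal_ofv(co, mod, params)
  # oracle: direct sum of Gaussian log-densities at eta = 0
  hp <- hazard_params("lognormal", mu = 2.5, sigma = 1.1)
  pred <- surv_prob(hp, co$obs$time)
  n_of <- co$arms$n[match(paste(co$obs$study_id, co$obs$arm_id),
                          paste(co$arms$study_id, co$arms$arm_id))]
  p_cl <- pmin(pmax(co$obs$obs_fraction, 0.5 / n_of), 1 - 0.5 / n_of)
  v <- (p_cl * (1 - p_cl) / n_of) * (pred^2 * 0.4^2 + 1.2^2)
  oracle <- -2 * sum(dnorm(co$obs$obs_fraction, pred, sqrt(v), log = TRUE))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("an exact-fit observation minimizes the OFV contribution", {
  hp <- hazard_params("lognormal", mu = 2.5, sigma = 1)
  mk <- function(frac) mbma_corpus(
    arm_row(), data.frame(study_id = "S1", arm_id = "A1", time = 12,
                          obs_fraction = frac))
  mod <- mbma_model("lognormal")
  params <- list(fixed = list(mu = 2.5, sigma = 1),
                 omega = c(mu = 0, sigma = 0),
                 eps = c(prop = 0.3, add = 1))
  exact <- surv_prob(hp, 12)
  o0 <- marginal_ofv(mk(exact), mod, params)
  for (delta in c(-0.1, -0.05, 0.05, 0.1))
    expect_gt(marginal_ofv(mk(exact + delta), mod, params), o0)
})

test_that("Laplace OFV agrees with 9-node adaptive Gauss-Hermite quadrature", {
  # 3-study toy corpus at moderate noise, fractions off the boundaries
  set.seed(21)
  truth <- generating_truth(
    covariate_effects = list(),
    design = list(arms = do.call(rbind, lapply(1:3, function(i)
      arm_row(study_id = paste0("S", i), n = 150L))),
      times = c(3, 6, 12, 24), s_min = 0, min_points = 3L))
  co <- generate_corpus(truth, seed = 3)
  stopifnot(all(co$obs$obs_fraction > 0 & co$obs$obs_fraction < 1))
  mod <- mbma_model("lognormal")
  params <- list(fixed = list(mu = 2.96, sigma = 0.999),
                 omega = c(mu = 0.159, sigma = 0.142),
                 eps = c(prop = 0.429, add = 1.241))
  lap <- marginal_ofv(co, mod, params)
  gh <- gh_ofv_oracle(co, mod, params)
  expect_lt(abs(lap - gh), 0.1)
  # also with a single random effect (1-d integral)
  params1 <- params; params1$omega <- c(mu = 0.159, sigma = 0)
  expect_lt(abs(marginal_ofv(co, mod, params1) -
                  gh_ofv_oracle(co, mod, params1)), 0.1)
})

test_that("OFV is invariant to study relabeling and row order", {
  co <- generate_corpus(parp_design(), seed = 4)
  mod <- published_model()
  params <- published_truth_params()
  o1 <- marginal_ofv(co, mod, params)
  # permute arm order (mbma_corpus re-sorts internally, so feed rows shuffled)
  set.seed(1)
  perm <- sample(nrow(co$obs))
  co2 <- mbma_corpus(co$arms[sample(nrow(co$arms)), ],
                     co$obs[perm, setdiff(names(co$obs), "se")])
  expect_equal(marginal_ofv(co2, mod, params), o1, tolerance = 1e-9)
  # relabel studies (reverse the names)
  map <- setNames(paste0("Z", 8:1), paste0("S", 1:8))
  arms3 <- co$arms; arms3$study_id <- unname(map[arms3$study_id])
  obs3 <- co$obs; obs3$study_id <- unname(map[obs3$study_id])
  co3 <- mbma_corpus(arms3, obs3[setdiff(names(obs3), "se")])
  expect_equal(marginal_ofv(co3, mod, params), o1, tolerance = 1e-9)
})

test_that("noiseless data recover the generating parameters to 1e-3", {
  truth <- generating_truth(
    mu = 2.7, sigma = 0.9, omega = c(mu = 0, sigma = 0),
    eps_prop = 0, eps_add = 0,
    covariate_effects = list(),
    design = list(arms = do.call(rbind, lapply(1:3, function(i)
      arm_row(study_id = paste0("S", i), n = 100L))),
      times = c(3, 6, 9, 12, 18, 24, 30), s_min = 0, min_points = 3L))
  co <- generate_corpus(truth, seed = 1)
  expect_equal(co$obs$obs_fraction,
               surv_prob(hazard_params("lognormal", mu = 2.7, sigma = 0.9),
                         co$obs$time))
  f <- fit_mbma(co, mbma_model("lognormal"), seed = 1, compute_se = FALSE)
  expect_lt(abs(f$theta[["mu"]] - 2.7), 1e-3)
  expect_lt(abs(f$theta[["sigma"]] - 0.9), 1e-3)
})

test_that("fit is reproducible and reports relative standard errors", {
  sf <- shared_fit()
  f <- sf$fit
  expect_true(f$converged)
  expect_true(is.finite(f$ofv))
  expect_equal(nrow(f$ebe), 8L)
  expect_equal(colnames(f$ebe), c("mu", "sigma"))
  f2 <- fit_mbma(sf$corpus, published_model(), seed = 1, compute_se = FALSE)
  expect_identical(f$theta, f2$theta)
  expect_identical(f$ofv, f2$ofv)
  # SEs on a separate (cheap) fit: relative SEs are positive percentages
  fse <- fit_mbma(sf$corpus, published_model(), seed = 1, compute_se = TRUE)
  expect_true(all(is.finite(fse$se_pct)))
  expect_true(all(fse$se_pct > 0))
})

test_that("empirical Bayes estimates shrink toward zero", {
  # negligible noise, eta = 0 truth: EBEs ~ 0
  truth <- generating_truth(
    mu = 2.7, sigma = 0.9, omega = c(mu = 0.1, sigma = 0.1),
    eps_prop = 1e-4, eps_add = 1e-4, covariate_effects = list(),
    design = list(arms = do.call(rbind, lapply(1:3, function(i)
      arm_row(study_id = paste0("S", i), n = 200L))),
      times = c(3, 6, 12, 24), s_min = 0, min_points = 3L))
  co <- generate_corpus(truth, seed = 2)
  # override the generator's eta draws with exact zeros
  obs_exact <- co$obs
  obs_exact$obs_fraction <- surv_prob(
    hazard_params("lognormal", mu = 2.7, sigma = 0.9), obs_exact$time)
  co0 <- mbma_corpus(co$arms, obs_exact[setdiff(names(obs_exact), "se")])
  o <- marginal_ofv(co0, mbma_model("lognormal"),
                    list(fixed = list(mu = 2.7, sigma = 0.9),
                         omega = c(mu = 0.1, sigma = 0.1),
                         eps = c(prop = 1e-4, add = 1e-4)), ebe = TRUE)
  expect_lt(max(abs(attr(o, "ebe"))), 1e-3)

  # EBE variance across many simulated studies does not exceed omega^2
  truth2 <- generating_truth(
    covariate_effects = list(),
    design = list(arms = do.call(rbind, lapply(1:50, function(i)
      arm_row(study_id = sprintf("S%02d", i), n = 100L))),
      times = seq(3, 36, 3), s_min = 0.02, min_points = 3L))
  co2 <- generate_corpus(truth2, seed = 9)
  o2 <- marginal_ofv(co2, mbma_model("lognormal"), published_truth_params()[
    c("fixed", "omega", "eps")], ebe = TRUE)
  ebe <- attr(o2, "ebe")
  expect_lt(var(ebe[, "mu"]), 0.159^2)
  expect_lt(var(ebe[, "sigma"]), 0.142^2)
})

test_that("omega -> 0 drives all EBEs to zero", {
  co <- exact_lognormal_corpus()
  o <- marginal_ofv(co, mbma_model("lognormal"),
                    list(fixed = list(mu = 2.4, sigma = 1),
                         omega = c(mu = 1e-6, sigma = 1e-6),
                         eps = c(prop = 0.3, add = 1)), ebe = TRUE)
  expect_lt(max(abs(attr(o, "ebe"))), 1e-5)
})

test_that("fit refuses a single-study corpus", {
  co <- exact_lognormal_corpus(n_studies = 1)
  expect_error(fit_mbma(co, mbma_model("lognormal")), ">= 2 studies")
})
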