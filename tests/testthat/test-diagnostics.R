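test_that("CWRES are standardized residuals on well-specified data", {
  sf <- shared_fit()
  g <- gof_tables(sf$fit, sf$corpus)
  expect_equal(nrow(g), nrow(sf$corpus$obs))
  expect_true(all(is.finite(g$cwres)))
  # data were simulated from (nearly) this model: CWRES ~ N(0, 1)
  expect_lt(abs(mean(g$cwres)), 0.15)
  expect_gt(sd(g$cwres), 0.8)
  expect_lt(sd(g$cwres), 1.2)
  # and evenly spread around zero, within 6
  expect_lt(max(abs(g$cwres)), 6)
  # IPRED tracks the observations more closely than PRED
  expect_lt(mean((g$obs - g$ipred)^2), mean((g$obs - g$pred)^2))
})

test_that("an exact-fit arm has zero residuals everywhere", {
  co <- exact_lognormal_corpus(n_studies = 3, mu = 2.4, sigma = 0.9)
  fit <- structure(list(
    family = "lognormal", model = mbma_model("lognormal"),
    theta = c(mu = 2.4, sigma = 0.9),
    omega = c(mu = 0.1, sigma = 0.1), eps = c(prop = 0.3, add = 1),
    ebe = matrix(0, 3, 2, dimnames = list(paste0("S", 1:3),
                                          c("mu", "sigma"))),
    effects = list(), converged = TRUE), class = "mbma_fit")
  g <- gof_tables(fit, co)
  expect_equal(g$pred, g$obs, tolerance = 1e-12)
  expect_equal(g$ipred, g$obs, tolerance = 1e-12)
  expect_lt(max(abs(g$cwres)), 1e-8)
})

test_that("VPC bands are ordered, seeded, and cover well-specified data", {
  sf <- shared_fit()
  v <- vpc(sf$fit, sf$corpus, n_sim = 150, seed = 11)
  expect_true(all(v$bands$p2.5 <= v$bands$p50 + 1e-12))
  expect_true(all(v$bands$p50 <= v$bands$p97.5 + 1e-12))
  # nominal 95% band covers at least 90% of the observations
  expect_gte(v$coverage, 0.90)
  # bit-identical under the same seed
  v2 <- vpc(sf$fit, sf$corpus, n_sim = 150, seed = 11)
  expect_identical(v$bands, v2$bands)
  expect_identical(v$coverage, v2$coverage)
  # a different seed gives different bands
  v3 <- vpc(sf$fit, sf$corpus, n_sim = 150, seed = 12)
  expect_false(identical(v$bands, v3$bands))
  # n_sim = 1 collapses the band onto the single replicate
  v1 <- vpc(sf$fit, sf$corpus, n_sim = 1, seed = 5)
  expect_equal(v1$bands$p2.5, v1$bands$p97.5, tolerance = 1e-12)
})

test_that("band ordering holds across seeds (property)", {
  sf <- shared_fit()
  for (s in 1:4) {
    v <- vpc(sf$fit, sf$corpus, n_sim = 40, seed = s)
    expect_true(all(diff(t(as.matrix(
      v$bands[c("p2.5", "p50", "p97.5")]))) >= -1e-12))
  }
})

test_that("bootstrap resamples studies, is seeded, and summarizes CIs", {
  sf <- shared_fit()
  b <- bootstrap_model(sf$corpus, published_model(), n = 8, seed = 3,
                       init = survmbma:::.fit_params(sf$fit))
  expect_lte(b$n_converged, b$n_requested)
  expect_equal(b$success_rate, 100 * b$n_converged / 8)
  expect_true(b$robust)
  # medians inside their own percentile intervals
  for (nm in names(b$param_medians)) {
    expect_gte(b$param_medians[nm], b$ci95["2.5%", nm])
    expect_lte(b$param_medians[nm], b$ci95["97.5%", nm])
  }
  b2 <- bootstrap_model(sf$corpus, published_model(), n = 8, seed = 3,
                        init = survmbma:::.fit_params(sf$fit))
  expect_identical(b$estimates, b2$estimates)
})

test_that("bootstrap of identical near-noiseless studies gives a tiny CI", {
  truth <- generating_truth(
    mu = 2.5, sigma = 1, omega = c(mu = 0, sigma = 0),
    eps_prop = 1e-3, eps_add = 1e-3, covariate_effects = list(),
    design = list(arms = do.call(rbind, lapply(1:4, function(i)
      arm_row(study_id = paste0("S", i), n = 200L))),
      times = c(3, 6, 12, 24), s_min = 0, min_points = 3L))
  co <- generate_corpus(truth, seed = 1)
  b <- bootstrap_model(co, mbma_model("lognormal"), n = 8, seed = 2)
  expect_lt(diff(b$ci95[, "mu"]), 0.05)
})

test_that("bootstrap 95% CI for mu covers the generating value", {
  # corpus generated at the published final-model parameters; the
  # study-resampling CI for the location parameter must cover the
  # generating mu = 2.96 (bootstrap size scaled down for runtime)
  sf <- shared_fit()
  b <- bootstrap_model(sf$corpus, published_model(), n = 40, seed = 1,
                       init = survmbma:::.fit_params(sf$fit))
  expect_gte(b$success_rate, 50)
  expect_lte(b$ci95["2.5%", "mu"], 2.96)
  expect_gte(b$ci95["97.5%", "mu"], 2.96)
})

test_that("sensitivity refit drops flagged arms and stays consistent", {
  sf <- shared_fit()
  r <- sensitivity_refit(sf$corpus, published_model(), full_fit = sf$fit,
                         seed = 1)
  expect_equal(r$n_dropped_arms, sum(!sf$corpus$arms$blinded))
  expect_true(r$fit$converged)
  # same generating model on the retained half: location parameters agree
  # within a generous stochastic tolerance
  expect_lt(abs(r$fit$theta[["mu"]] / sf$fit$theta[["mu"]] - 1), 0.25)
  expect_lt(abs(r$fit$theta[["sigma"]] / sf$fit$theta[["sigma"]] - 1), 0.25)

  # nothing flagged: estimates match the full fit
  arms_all <- sf$corpus$arms; arms_all$blinded <- TRUE
  co_all <- mbma_corpus(arms_all,
                        sf$corpus$obs[setdiff(names(sf$corpus$obs), "se")])
  r2 <- sensitivity_refit(co_all, published_model(), full_fit = sf$fit,
                          seed = 1)
  expect_equal(r2$fit$theta, sf$fit$theta, tolerance = 1e-4)

  # everything flagged: explicit refusal
  arms_none <- sf$corpus$arms; arms_none$blinded <- FALSE
  co_none <- mbma_corpus(arms_none,
                         sf$corpus$obs[setdiff(names(sf$corpus$obs), "se")])
  expect_error(sensitivity_refit(co_none, published_model()), "all .* arms")
})
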