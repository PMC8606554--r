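test_that("apply_covariate implements the categorical and continuous forms", {
  combo <- covariate_effect("therapy_type", kind = "categorical",
                            theta = c(monotherapy = -0.215),
                            reference = "combination")
  expect_equal(apply_covariate(2.96, list(therapy_type = "monotherapy"),
                               list(combo)), 2.96 * (1 - 0.215))
  expect_equal(apply_covariate(2.96, list(therapy_type = "monotherapy"),
                               list(combo)), 2.3236)
  # reference level leaves the typical value unchanged
  expect_equal(apply_covariate(2.96, list(therapy_type = "combination"),
                               list(combo)), 2.96)
  # continuous covariate at its median is the identity
  age <- covariate_effect("median_age", kind = "continuous", theta = 0.02,
                          cov_median = 58)
  expect_equal(apply_covariate(2.96, list(median_age = 58), list(age)), 2.96)
  expect_equal(apply_covariate(2.96, list(median_age = 63), list(age)),
               2.96 * exp(5 * 0.02))
  # theta = 0 is the identity for both kinds
  z_cat <- covariate_effect("drug", kind = "categorical",
                            theta = c(niraparib = 0, rucaparib = 0),
                            reference = "olaparib")
  z_con <- covariate_effect("median_age", kind = "continuous", theta = 0,
                            cov_median = 60)
  for (prof in list(list(drug = "niraparib", median_age = 70),
                    list(drug = "olaparib", median_age = 50)))
    expect_equal(apply_covariate(1.7, prof, list(z_cat, z_con)), 1.7)
  # effects compose multiplicatively
  expect_equal(
    apply_covariate(2.96, list(therapy_type = "monotherapy",
                               median_age = 63), list(combo, age)),
    2.96 * (1 - 0.215) * exp(5 * 0.02))
  expect_error(apply_covariate(2, list(median_age = 60),
                               list(covariate_effect("ecog0_pct",
                                                     kind = "continuous",
                                                     theta = 0.1,
                                                     cov_median = 70))),
               "lacks covariate")
})

test_that("impute_missing fills blanks with the n-weighted median", {
  arms <- rbind(arm_row(study_id = "S1", n = 100L, median_age = 58),
                arm_row(study_id = "S2", n = 100L, median_age = NA),
                arm_row(study_id = "S3", n = 100L, median_age = 61))
  obs <- do.call(rbind, lapply(1:3, function(i)
    data.frame(study_id = paste0("S", i), arm_id = "A1", time = c(3, 6),
               obs_fraction = c(0.9, 0.7))))
  co <- mbma_corpus(arms, obs)
  r <- impute_missing(co, "median_age")
  expect_equal(r$report$imputed_value, 59.5)
  expect_equal(r$corpus$arms$median_age[r$corpus$arms$study_id == "S2"],
               59.5)
  # no blanks: corpus unchanged
  r2 <- impute_missing(r$corpus, "median_age")
  expect_equal(r2$corpus$arms, r$corpus$arms)
  expect_equal(r2$report$n_imputed, 0L)
})

test_that("covariates missing in > 30% of patients are untestable", {
  arms <- rbind(arm_row(study_id = "S1", n = 120L, median_age = NA),
                arm_row(study_id = "S2", n = 180L, median_age = 60))
  obs <- do.call(rbind, lapply(1:2, function(i)
    data.frame(study_id = paste0("S", i), arm_id = "A1", time = c(3, 6),
               obs_fraction = c(0.9, 0.7))))
  co <- mbma_corpus(arms, obs)
  r <- impute_missing(co, "median_age")  # 40% of patients missing
  expect_false(r$report$testable)
  # still imputed -- the flag only removes it from stepwise candidacy
  expect_equal(r$corpus$arms$median_age[1], 60)
  # all missing: untestable as well
  arms$median_age <- NA_real_
  r3 <- impute_missing(mbma_corpus(arms, obs), "median_age")
  expect_false(r3$report$testable)
})

test_that("selection with no candidates returns the base model untouched", {
  sf <- shared_fit()
  sel <- select_covariates(sf$corpus, mbma_model("lognormal"), list(),
                           seed = 1, compute_se = FALSE)
  expect_equal(nrow(sel$trace), 0L)
  expect_length(sel$selected, 0L)
  expect_true(sel$fit$converged)
})

test_that("selection trace obeys the forward/backward thresholds", {
  sf <- shared_fit()
  co <- sf$corpus
  set.seed(77)
  co$arms$z_noise <- rnorm(nrow(co$arms))
  co2 <- mbma_corpus(co$arms, co$obs[setdiff(names(co$obs), "se")])
  sel <- select_covariates(co2, mbma_model("lognormal"),
                           c("therapy_type", "z_noise"), seed = 1,
                           compute_se = FALSE)
  tr <- sel$trace
  # every forward acceptance exceeded the 2.71 entry threshold
  acc <- tr[tr$phase == "forward" & tr$action == "accepted", ]
  expect_true(all(acc$delta > 2.71))
  # every backward removal failed the 3.84 retention threshold
  rem <- tr[tr$phase == "backward" & tr$action == "removed", ]
  if (nrow(rem)) expect_true(all(-rem$delta <= 3.84))
  # covariates retained at the end all raise the OFV by > 3.84 on removal
  last_bw <- tr[tr$phase == "backward" & tr$action == "tested", ]
  for (cv in sel$selected) {
    rises <- -last_bw$delta[last_bw$candidate == cv]
    expect_true(all(rises > 3.84))
  }
  # the generating covariate is selected on this corpus
  expect_true("therapy_type" %in% sel$selected)
})
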