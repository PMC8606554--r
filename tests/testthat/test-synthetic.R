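test_that("generation is seeded: same seed identical, different seed not", {
  t1 <- generate_corpus(parp_design(), seed = 5)
  t2 <- generate_corpus(parp_design(), seed = 5)
  t3 <- generate_corpus(parp_design(), seed = 6)
  expect_identical(t1$obs, t2$obs)
  expect_identical(attr(t1, "truth_record")$eta,
                   attr(t2, "truth_record")$eta)
  expect_false(identical(attr(t1, "truth_record")$eta,
                         attr(t3, "truth_record")$eta))
})

test_that("every generated corpus passes the corpus validation rules", {
  for (s in 1:5) {
    co <- generate_corpus(parp_design(), seed = s)
    expect_silent(validate_corpus(co))
    expect_true(all(co$obs$obs_fraction >= 0 & co$obs$obs_fraction <= 1))
  }
})

test_that("the default design reproduces the published patient margins", {
  co <- generate_corpus(parp_design(), seed = 1)
  s <- summarize_corpus(co)
  g <- function(v, l) s$patients[s$variable == v & s$level == l]
  expect_identical(g("drug", "olaparib"), 501L)
  expect_identical(g("drug", "niraparib"), 302L)
  expect_identical(g("drug", "rucaparib"), 366L)
  expect_identical(g("biomarker", "BRCAm"), 669L)
  expect_identical(g("biomarker", "BRCAwt"), 100L)
  expect_identical(g("biomarker", "HRD_positive"), 400L)
  expect_identical(g("therapy_type", "monotherapy"), 1077L)
  expect_identical(g("therapy_type", "combination"), 92L)
  expect_identical(g("platinum", "partially_resistant"), 64L)
  expect_identical(g("partner", "bevacizumab"), 21L)
  expect_identical(g("partner", "cediranib"), 43L)
  expect_identical(g("partner", "chemotherapy"), 28L)
  expect_identical(sum(co$arms$n), 1169L)
  expect_identical(length(unique(co$arms$study_id)), 8L)
  expect_identical(nrow(co$arms), 12L)
  # four of the eight studies are open-label
  open <- tapply(!co$arms$blinded, co$arms$study_id, any)
  expect_identical(sum(open), 4L)
})

test_that("all-zero variance components reproduce the survival curve", {
  truth <- generating_truth(
    mu = 2.96, sigma = 0.999, omega = c(mu = 0, sigma = 0),
    eps_prop = 0, eps_add = 0)
  co <- generate_corpus(truth, seed = 3)
  mono <- hazard_params("lognormal", mu = 2.3236, sigma = 0.999)
  combo <- hazard_params("lognormal", mu = 2.96, sigma = 0.999)
  for (a in seq_len(nrow(co$arms))) {
    sel <- co$obs$study_id == co$arms$study_id[a] &
      co$obs$arm_id == co$arms$arm_id[a]
    hp <- if (co$arms$therapy_type[a] == "monotherapy") mono else combo
    expect_equal(co$obs$obs_fraction[sel], surv_prob(hp, co$obs$time[sel]),
                 tolerance = 1e-12)
  }
})

test_that("the residual model is calibrated before clipping", {
  # standardized latent residuals (Obs_latent - Pred) / SE should have mean
  # ~0 and pointwise SD ~ sqrt(Pred^2 eps_prop^2 + eps_add^2)
  truth <- parp_design()
  z <- list(); expected_sd <- list()
  for (s in 1:30) {
    lat <- attr(generate_corpus(truth, seed = 400 + s), "truth_record")$latent
    z[[s]] <- (lat$obs_latent - lat$pred) / lat$se_gen
    expected_sd[[s]] <- sqrt(lat$pred^2 * 0.429^2 + 1.241^2)
  }
  z <- unlist(z); expected_sd <- unlist(expected_sd)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) / sqrt(mean(expected_sd^2)) - 1), 0.05)
  # high-prediction points carry the proportional component: their SD
  # exceeds the additive floor
  hi <- expected_sd > quantile(expected_sd, 0.9)
  expect_gt(sd(z[hi]), 1.241)
})

test_that("between-study spread of generated medians matches omega_mu", {
  # many single-arm studies; the SD of log arm median PFS across studies
  # approaches mu * omega_mu (eta multiplies mu, so log median = mu * e^eta)
  # grid extended far enough that every study's curve crosses one half
  design <- list(arms = do.call(rbind, lapply(1:200, function(i)
    arm_row(study_id = sprintf("S%03d", i), n = 100L))),
    times = seq(3, 240, 3), s_min = 0.02, min_points = 3L)
  truth <- generating_truth(covariate_effects = list(), design = design,
                            eps_prop = 0, eps_add = 0)
  co <- generate_corpus(truth, seed = 31)
  # observed arm medians by interpolating the (noise-free) curve crossings
  log_med <- vapply(unique(co$obs$study_id), function(s) {
    i <- co$obs$study_id == s
    log(stats::approx(co$obs$obs_fraction[i], co$obs$time[i],
                      xout = 0.5)$y)
  }, 0)
  # eta multiplies mu, so log median PFS = mu * exp(eta): its SD across
  # studies approaches mu * omega_mu
  expect_lt(abs(sd(log_med) / (2.96 * 0.159) - 1), 0.20)
})

test_that("deep-tail observations are truncated from the grid", {
  # a fast-progressing truth pushes late survival below the 2% floor
  truth <- generating_truth(mu = 1.2, sigma = 0.5,
                            omega = c(mu = 0, sigma = 0),
                            eps_prop = 0, eps_add = 0,
                            covariate_effects = list())
  co <- generate_corpus(truth, seed = 1)
  expect_lt(max(co$obs$time), 36)
  # but never below the minimum retained points
  counts <- table(paste(co$obs$study_id, co$obs$arm_id))
  expect_true(all(counts >= 3))
})
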