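## Synthetic corpora with the exact statistical structure the analysis
## assumes: study-level random effects, covariate scaling, and the
## SE-weighted proportional + additive residual model. The default design
## reproduces the arm layout and patient margins of the PARP-inhibitor
## maintenance meta-analysis this package was built around (8 studies,
## 12 arms, 1,169 patients), so pipeline tests have a realistic target
## without any external data.

#' Generating truth for a synthetic corpus
#'
#' @param family hazard family of the generating model.
#' @param mu,sigma log-normal log-time location and scale (lognormal family).
#' @param lambda0,beta baseline hazard and shape (other families).
#' @param covariate_effects list of [covariate_effect()] objects with thetas
#'   set; defaults to the monotherapy-vs-combination effect on `mu`.
#' @param omega named between-study SDs of the multiplicative study effects
#'   (`mu`, `sigma` for lognormal; `lambda0` otherwise).
#' @param eps_prop,eps_add residual SDs of the proportional and additive
#'   components (both scaled by the binomial SE of the observation).
#' @param design list with `arms` (arm table as in [mbma_corpus()]),
#'   `times` (observation grid in months) and `s_min` (observations with a
#'   noiseless prediction below this survival level are truncated away, as
#'   published curves rarely extend into deep tails; at least `min_points`
#'   early points are always kept).
#' @return an object of class `generating_truth`.
#' @export
generating_truth <- function(family = "lognormal", mu = 2.96, sigma = 0.999,
                             lambda0 = NULL, beta = NULL,
                             covariate_effects = list(
                               covariate_effect(
                                 "therapy_type", target = "mu",
                                 kind = "categorical",
                                 theta = c(monotherapy = -0.215),
                                 reference = "combination")),
                             omega = c(mu = 0.159, sigma = 0.142),
                             eps_prop = 0.429, eps_add = 1.241,
                             design = parp_design_arms()) {
  family <- match.arg(family, .hazard_families)
  fixed <- switch(family,
    lognormal    = list(mu = mu, sigma = sigma),
    exponential  = list(lambda0 = lambda0),
    gompertz     = list(lambda0 = lambda0, beta = beta),
    weibull_form = list(lambda0 = lambda0, beta = beta))
  if (any(vapply(fixed, is.null, TRUE)))
    stop_config("generating_truth: family '", family,
                "' needs its parameters set")
  info <- .family_info(family)
  om <- stats::setNames(rep(0, length(info$re)), info$re)
  ov <- unlist(omega)
  om[intersect(names(ov), info$re)] <- ov[intersect(names(ov), info$re)]
  if (any(om < 0) || eps_prop < 0 || eps_add < 0)
    stop_config("generating_truth: variance components must be >= 0")
  structure(list(family = family, fixed = fixed,
                 covariate_effects = covariate_effects, omega = om,
                 eps_prop = eps_prop, eps_add = eps_add, design = design),
            class = "generating_truth")
}

#' Default meta-analytic design: arm table and observation grid
#'
#' A deterministic 8-study / 12-arm / 1,169-patient layout whose margins
#' match the source meta-analysis: drug totals 501 olaparib / 302 niraparib /
#' 366 rucaparib, biomarker totals 669 BRCAm / 100 BRCAwt / 400
#' HRD-positive, 1,077 monotherapy vs 92 combination (43 cediranib, 28
#' chemotherapy, 21 bevacizumab), 1,105 platinum-sensitive vs 64 partially
#' platinum-resistant, and four of the eight studies open-label.
#'
#' @return list with `arms`, `times` (3 to 36 months by 3), `s_min` (0.02)
#'   and `min_points` (3).
#' @export
parp_design_arms <- function() {
  arms <- data.frame(
    study_id = c("S1", "S1", "S2", "S3", "S4", "S5", "S6", "S6",
                 "S7", "S7", "S8", "S8"),
    arm_id = c("A1", "A2", "A1", "A1", "A1", "A1", "A1", "A2",
               "A1", "A2", "A1", "A2"),
    n = c(180L, 100L, 150L, 43L, 28L, 21L, 117L, 164L,
          130L, 108L, 64L, 64L),
    therapy_type = c("monotherapy", "monotherapy", "monotherapy",
                     "combination", "combination", "combination",
                     "monotherapy", "monotherapy", "monotherapy",
                     "monotherapy", "monotherapy", "monotherapy"),
    drug = c("olaparib", "olaparib", "olaparib", "olaparib", "olaparib",
             "niraparib", "niraparib", "niraparib", "rucaparib",
             "rucaparib", "rucaparib", "rucaparib"),
    biomarker = c("BRCAm", "BRCAwt", "BRCAm", "BRCAm", "BRCAm", "BRCAm",
                  "BRCAm", "HRD_positive", "BRCAm", "HRD_positive",
                  "HRD_positive", "HRD_positive"),
    platinum = c(rep("sensitive", 11), "partially_resistant"),
    partner = c("none", "none", "none", "cediranib", "chemotherapy",
                "bevacizumab", "none", "none", "none", "none", "none",
                "none"),
    ecog0_pct = c(70, 70, 70, 70, 70, 70, 70, 70, 70, 70, 70, 70),
    median_age = c(58, 61, 58, 58, 58, 58, 58, 66, 58, 66, 66, 66),
    blinded = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE,
                TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  list(arms = arms, times = seq(3, 36, by = 3), s_min = 0.02,
       min_points = 3L)
}

#' Ready-made generating truth at the published final-model parameters
#'
#' Convenience wrapper: [generating_truth()] with its defaults, i.e. the
#' log-normal final model (`mu` 2.96, `sigma` 0.999, monotherapy effect
#' -0.215 on `mu`, between-study SDs 0.159 / 0.142, residual SDs 0.429
#' proportional and 1.241 additive) over the default design.
#'
#' @return a `generating_truth`.
#' @export
parp_design <- function() generating_truth()

#' Generate a synthetic corpus from a generating truth
#'
#' Per study, draws the random effect vector `eta ~ N(0, omega^2)`; per arm,
#' scales the typical parameters through the covariate engine and `exp(eta)`;
#' per time point, computes the noiseless prediction `Pred = S(t)`, its
#' binomial standard error `SE = sqrt(Pred (1 - Pred) / n)`, and the noisy
#' observation `Obs = Pred (1 + SE eps1) + SE eps2`, clipped to `[0, 1]`.
#' The unclipped latent values and all latent draws are attached as the
#' `truth_record` attribute for recovery and calibration testing.
#'
#' @param truth a [generating_truth()].
#' @param seed integer seed; the same seed reproduces the corpus exactly.
#' @return an `mbma_corpus` with attribute `truth_record` (list: `eta`
#'   data.frame, `latent` data.frame with `pred`, `se_gen`, `obs_latent`,
#'   `truth`, `seed`).
#' @export
generate_corpus <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "generating_truth"))
  arms <- truth$design$arms
  info <- .family_info(truth$family)
  resolved <- .resolve_effects(truth$covariate_effects, arms)
  theta <- stats::setNames(
    as.list(unlist(lapply(resolved$terms, `[[`, "theta"))),
    resolved$theta_names)
  mult <- .cov_multipliers(resolved, arms, theta)
  studies <- unique(arms$study_id)
  with_seed(seed, {
    eta <- matrix(stats::rnorm(length(studies) * length(info$re)),
                  length(studies), length(info$re),
                  dimnames = list(studies, info$re))
    eta <- sweep(eta, 2L, truth$omega[info$re], `*`)
    rows <- list()
    latent <- list()
    for (a in seq_len(nrow(arms))) {
      e <- stats::setNames(eta[arms$study_id[a], ], colnames(eta))
      pv <- list()
      for (nm in info$fixed) {
        val <- truth$fixed[[nm]] * (mult[[nm]][a] %||% 1)
        if (is.null(mult[[nm]])) val <- truth$fixed[[nm]]
        if (nm %in% info$re) val <- val * exp(e[[nm]])
        pv[[nm]] <- val
      }
      hp <- do.call(hazard_params, c(list(family = truth$family), pv))
      tt <- truth$design$times
      pred <- surv_prob(hp, tt)
      keep <- pred >= truth$design$s_min
      keep[seq_len(min(truth$design$min_points, length(tt)))] <- TRUE
      tt <- tt[keep]; pred <- pred[keep]
      se_gen <- sqrt(pred * (1 - pred) / arms$n[a])
      e1 <- stats::rnorm(length(tt), 0, truth$eps_prop)
      e2 <- stats::rnorm(length(tt), 0, truth$eps_add)
      obs_latent <- pred * (1 + se_gen * e1) + se_gen * e2
      obs <- pmin(pmax(obs_latent, 0), 1)
      rows[[a]] <- data.frame(
        study_id = arms$study_id[a], arm_id = arms$arm_id[a], time = tt,
        obs_fraction = obs, pred_fraction = pred, stringsAsFactors = FALSE)
      latent[[a]] <- data.frame(
        study_id = arms$study_id[a], arm_id = arms$arm_id[a], time = tt,
        pred = pred, se_gen = se_gen, obs_latent = obs_latent,
        stringsAsFactors = FALSE)
    }
    corpus <- mbma_corpus(arms, do.call(rbind, rows),
                          meta = list(synthetic = TRUE, seed = seed))
    attr(corpus, "truth_record") <- list(
      eta = as.data.frame(eta), latent = do.call(rbind, latent),
      truth = truth, seed = seed)
    corpus
  })
}
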