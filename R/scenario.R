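## Scenario machinery: arm-level parameter summaries, random-effects
## pooling per scenario (DerSimonian-Laird), and Monte-Carlo simulation of
## progression-free-survival bands and median PFS with confidence interval.

#' Arm-level location-parameter estimates
#'
#' For each arm: the covariate-adjusted typical value of the family's
#' location parameter (`mu` for log-normal, `lambda0` otherwise) times the
#' study's empirical Bayes multiplier `exp(eta)`, with a delta-method
#' standard error from the EBE conditional variance.
#'
#' @param fit a converged `mbma_fit`.
#' @param corpus the corpus the fit describes.
#' @return data.frame with one row per arm: `study_id`, `arm_id`, `n`,
#'   `mu_i`, `se_mu_i`, and the scenario-label columns (`therapy_type`,
#'   `drug`, `biomarker`, `platinum`, `partner`).
#' @export
arm_parameters <- function(fit, corpus) {
  stopifnot(inherits(fit, "mbma_fit"))
  validate_corpus(corpus)
  arms <- corpus$arms
  loc <- if (fit$family == "lognormal") "mu" else "lambda0"
  eff <- Filter(function(e) e$target == loc, fit$effects %||% list())
  mu_i <- se_i <- numeric(nrow(arms))
  for (a in seq_len(nrow(arms))) {
    s <- arms$study_id[a]
    base <- apply_covariate(fit$theta[[loc]], arms[a, , drop = FALSE], eff)
    eta <- if (s %in% rownames(fit$ebe)) fit$ebe[s, loc] else 0
    v <- if (s %in% rownames(fit$ebe)) fit$ebe_var[s, loc] else 0
    mu_i[a] <- base * exp(eta)
    ## d(mu_i)/d(eta) = mu_i, so se = mu_i * sd(eta | data); floored so
    ## degenerate (omega = 0) fits still pool
    se_i[a] <- max(mu_i[a] * sqrt(max(v, 0, na.rm = TRUE)),
                   mu_i[a] * 1e-6)
  }
  cbind(data.frame(study_id = arms$study_id, arm_id = arms$arm_id,
                   n = arms$n, mu_i = mu_i, se_mu_i = se_i,
                   stringsAsFactors = FALSE),
        arms[, intersect(c("therapy_type", "drug", "biomarker", "platinum",
                           "partner"), names(arms)), drop = FALSE])
}

#' Random-effects pooling of arm-level estimates for one scenario
#'
#' DerSimonian-Laird single-arm meta-analysis of the arm location
#' parameters within a scenario, with weights `1/(se_i^2 + tau^2)`. The
#' confidence interval is `pooled +/- z * SE_pooled`. A single-arm scenario
#' returns that arm's estimate and its z-interval with `tau2 = 0`.
#'
#' @param arms data.frame from [arm_parameters()].
#' @param scenario named list of covariate filters, e.g.
#'   `list(therapy_type = "monotherapy", drug = "olaparib")`. Values may be
#'   vectors (match any).
#' @param level confidence level in percent (default 90, the level used for
#'   scenario intervals).
#' @return an object of class `mbma_pool`: `scenario`, `k` (arms pooled),
#'   `pooled`, `se`, `ci` (length 2), `tau2`, `level`, `arms`.
#' @export
random_effects_pool <- function(arms, scenario = list(), level = 90) {
  keep <- rep(TRUE, nrow(arms))
  for (nm in names(scenario)) {
    if (!nm %in% names(arms))
      stop_config("random_effects_pool: no scenario column '", nm, "'")
    keep <- keep & arms[[nm]] %in% scenario[[nm]]
  }
  lab <- if (length(scenario))
    paste(names(scenario), vapply(scenario, paste, "", collapse = "|"),
          sep = "=", collapse = ", ") else "all arms"
  if (!any(keep))
    stop_config("random_effects_pool: no arms match scenario [", lab, "]")
  sub <- arms[keep, , drop = FALSE]
  z <- stats::qnorm((1 + level / 100) / 2)
  if (nrow(sub) == 1L) {
    pooled <- sub$mu_i[1L]; se <- sub$se_mu_i[1L]; tau2 <- 0
  } else {
    r <- metafor::rma.uni(yi = sub$mu_i, sei = sub$se_mu_i, method = "DL")
    pooled <- as.numeric(r$beta); se <- r$se; tau2 <- r$tau2
  }
  structure(list(scenario = lab, k = nrow(sub), pooled = pooled, se = se,
                 ci = c(pooled - z * se, pooled + z * se), tau2 = tau2,
                 level = level, arms = sub),
            class = "mbma_pool")
}

#' @export
print.mbma_pool <- function(x, ...) {
  cat(sprintf("<mbma_pool> [%s] k=%d pooled=%.4f (%d%% CI %.4f-%.4f) tau2=%.4g\n",
              x$scenario, x$k, x$pooled, x$level, x$ci[1], x$ci[2], x$tau2))
  invisible(x)
}

#' Monte-Carlo simulation of PFS for one scenario
#'
#' Draws the location parameter from `Normal(pooled, se)` per replicate
#' (`se` implied by the pooled confidence interval), computes the survival
#' curve on the time grid and the median survival time of each replicate,
#' and summarizes the per-time and median-PFS distributions by their median
#' and the `level`% equal-tailed band.
#'
#' @param pooled an `mbma_pool` (or a list with `pooled`, `se`, `level`).
#' @param sigma log-normal scale parameter, held at its population estimate.
#' @param n_rep number of Monte-Carlo replicates (default 10000).
#' @param time_grid months.
#' @param seed integer seed; output is exactly reproducible.
#' @param family hazard family (`"lognormal"` uses the closed-form median
#'   `exp(mu)`; `"exponential"` uses `log(2)/lambda0`; other families solve
#'   `S(t) = 0.5` numerically and need `fixed_other`).
#' @param fixed_other named list of the family's remaining fixed parameters
#'   (e.g. `beta`), for the non-log-normal families.
#' @return an object of class `scenario_summary`: `scenario`, `pooled_mu`,
#'   `ci_mu`, `tau2`, `pfs_band` (data.frame `time`, `lo`, `median`, `hi`),
#'   `median_pfs` (named: `median`, `lo`, `hi`), `level`, `n_rep`, `seed`.
#' @export
simulate_scenario <- function(pooled, sigma = NULL, n_rep = 10000L,
                              time_grid = seq(0.5, 42, by = 0.5), seed = 1L,
                              family = "lognormal", fixed_other = NULL) {
  stopifnot(n_rep >= 1L)
  family <- match.arg(family, .hazard_families)
  if (family == "lognormal" && is.null(sigma))
    stop_config("simulate_scenario: sigma required for the lognormal family")
  level <- pooled$level %||% 90
  pq <- c((1 - level / 100) / 2, 0.5, (1 + level / 100) / 2)
  draws <- with_seed(seed, stats::rnorm(n_rep, pooled$pooled, pooled$se))
  hp_of <- function(m) switch(family,
    lognormal    = hazard_params("lognormal", mu = m, sigma = sigma),
    exponential  = hazard_params("exponential", lambda0 = m),
    gompertz     = hazard_params("gompertz", lambda0 = m,
                                 beta = fixed_other$beta),
    weibull_form = hazard_params("weibull_form", lambda0 = m,
                                 beta = fixed_other$beta))
  if (family == "lognormal") {
    S <- vapply(time_grid, function(tt)
      pnorm((log(tt) - draws) / sigma, lower.tail = FALSE), numeric(n_rep))
    med <- exp(draws)
  } else {
    if (any(draws <= 0))
      stop_config("simulate_scenario: non-positive hazard draw; the pooled ",
                  "distribution is too wide for this family")
    S <- t(vapply(draws, function(m) surv_prob(hp_of(m), time_grid),
                  numeric(length(time_grid))))
    med <- vapply(draws, function(m) median_surv_time(hp_of(m)), 0)
  }
  S <- matrix(S, nrow = n_rep)
  bands <- t(apply(S, 2L, stats::quantile, probs = pq, names = FALSE))
  mq <- stats::quantile(med, pq, names = FALSE)
  structure(list(scenario = pooled$scenario %||% "custom",
                 pooled_mu = pooled$pooled,
                 ci_mu = pooled$ci %||% rep(pooled$pooled, 2),
                 tau2 = pooled$tau2 %||% NA_real_,
                 pfs_band = data.frame(time = time_grid, lo = bands[, 1],
                                       median = bands[, 2], hi = bands[, 3]),
                 median_pfs = c(median = mq[2], lo = mq[1], hi = mq[3]),
                 level = level, n_rep = n_rep, seed = seed),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "<scenario_summary> [%s] median PFS %.2f months (%d%% CI %.2f-%.2f), %d reps\n",
    x$scenario, x$median_pfs[["median"]], x$level, x$median_pfs[["lo"]],
    x$median_pfs[["hi"]], x$n_rep))
  invisible(x)
}

#' Pool and simulate a set of scenarios
#'
#' Convenience wrapper: [arm_parameters()], then per scenario
#' [random_effects_pool()] and [simulate_scenario()], collected into a
#' summary table (scenario, arms pooled, pooled location, median PFS and
#' band).
#'
#' @param fit a converged log-normal `mbma_fit`.
#' @param corpus the corpus the fit describes.
#' @param scenarios named list of scenario filters (each a named list, see
#'   [random_effects_pool()]).
#' @param n_rep,seed,level passed through.
#' @return list with `table` (data.frame) and `details` (list of
#'   `scenario_summary`).
#' @export
simulate_scenarios <- function(fit, corpus, scenarios, n_rep = 10000L,
                               seed = 1L, level = 90) {
  ap <- arm_parameters(fit, corpus)
  sig <- fit$theta[["sigma"]]
  details <- vector("list", length(scenarios))
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    pl <- random_effects_pool(ap, scenarios[[i]], level = level)
    sm <- simulate_scenario(pl, sigma = sig, n_rep = n_rep,
                            seed = seed + i, family = fit$family)
    details[[i]] <- sm
    rows[[i]] <- data.frame(
      scenario = names(scenarios)[i] %||% pl$scenario, k = pl$k,
      pooled_mu = pl$pooled, tau2 = pl$tau2,
      median_pfs = sm$median_pfs[["median"]],
      ci_lo = sm$median_pfs[["lo"]], ci_hi = sm$median_pfs[["hi"]],
      stringsAsFactors = FALSE)
  }
  names(details) <- names(scenarios)
  list(table = do.call(rbind, rows), details = details)
}
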