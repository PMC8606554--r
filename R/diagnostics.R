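## Model evaluation: goodness-of-fit residual tables, visual predictive
## check, study-level nonparametric bootstrap, and the open-label
## sensitivity refit.

## predictions for every observation at given per-study eta (matrix or zero)
.predict_obs <- function(prep, params, eta_mat = NULL) {
  info <- prep$info
  mult <- .cov_multipliers(prep$resolved, prep$arms,
                           as.list(params$theta[prep$resolved$theta_names]))
  out <- numeric(nrow(prep$obs))
  for (si in seq_along(prep$studies)) {
    blk <- prep$blocks[[si]]
    base <- .base_params(prep$family, unlist(params$fixed), mult, prep$arms,
                         blk)
    eta <- if (is.null(eta_mat)) rep(0, length(info$re)) else
      eta_mat[prep$studies[si], info$re]
    d <- .study_dat(prep$family, blk, base, params$eps[["prop"]]^2,
                    params$eps[["add"]]^2, rep(1, length(info$re)),
                    list(all = info$re, which = seq_along(info$re)))
    out[blk$idx] <- .surv_at(eta, d, seq_along(blk$t))
  }
  out
}

#' Goodness-of-fit residual table
#'
#' Per observation: the observed fraction, the population prediction PRED
#' (study effects at zero), the individual prediction IPRED (study effects
#' at their empirical Bayes estimates), and conditional weighted residuals
#' CWRES from a first-order linearization of the model around the EBE with
#' the combined residual covariance (residuals decorrelated within study).
#'
#' @param fit a converged `mbma_fit`.
#' @param corpus the corpus the fit describes.
#' @return data.frame with columns `study_id`, `arm_id`, `time`, `obs`,
#'   `pred`, `ipred`, `res`, `cwres`.
#' @export
gof_tables <- function(fit, corpus) {
  stopifnot(inherits(fit, "mbma_fit"))
  prep <- .prep_fit(corpus, fit$model)
  ## residual tables include boundary observations like interior ones
  for (si in seq_along(prep$blocks)) prep$blocks[[si]]$cens[] <- 0L
  params <- .normalize_params(.fit_params(fit), prep)
  info <- prep$info
  pred <- .predict_obs(prep, params)
  ipred <- .predict_obs(prep, params, eta_mat = fit$ebe)
  cwres <- numeric(nrow(prep$obs))
  omega2 <- params$omega[info$re]^2
  for (si in seq_along(prep$studies)) {
    blk <- prep$blocks[[si]]
    mult <- .cov_multipliers(prep$resolved, prep$arms,
                             as.list(params$theta[prep$resolved$theta_names]))
    base <- .base_params(prep$family, unlist(params$fixed), mult, prep$arms,
                         blk)
    d <- .study_dat(prep$family, blk, base, params$eps[["prop"]]^2,
                    params$eps[["add"]]^2, rep(1, length(info$re)),
                    list(all = info$re, which = seq_along(info$re)))
    eta_hat <- fit$ebe[prep$studies[si], info$re]
    cv <- .score_core(eta_hat, d)
    ## FOCE-style linearization: E[y] ~ f(eta_hat) - G eta_hat,
    ## Cov = G Omega G' + diag(V)
    G <- cv$dS
    Cov <- G %*% diag(omega2, length(info$re)) %*% t(G) + diag(cv$V)
    ee <- eigen(Cov, symmetric = TRUE)
    inv_sqrt <- ee$vectors %*% diag(1 / sqrt(pmax(ee$values, 1e-300)),
                                    nrow(Cov)) %*% t(ee$vectors)
    resid <- blk$obs - (cv$S - as.numeric(G %*% eta_hat))
    cwres[blk$idx] <- as.numeric(inv_sqrt %*% resid)
  }
  data.frame(study_id = prep$obs$study_id, arm_id = prep$obs$arm_id,
             time = prep$obs$time, obs = prep$obs$obs_fraction,
             pred = pred, ipred = ipred, res = prep$obs$obs_fraction - pred,
             cwres = cwres, stringsAsFactors = FALSE)
}

#' Visual predictive check
#'
#' Simulates `n_sim` corpus replicates from the fitted model (new study
#' effects per study, new residuals per observation with each observation's
#' weighting SE), computes the 2.5/50/97.5 percentile band of the simulated
#' fractions for every design point (arm by time), and reports the share of
#' observed points inside their 95% band. Percentiles are computed from the
#' untruncated simulated values; a `[0, 1]`-truncated copy is returned for
#' plotting.
#'
#' @param fit a converged `mbma_fit`.
#' @param corpus the corpus the fit describes.
#' @param n_sim number of simulated replicates (default 1000).
#' @param seed integer seed; results are exactly reproducible.
#' @return an object of class `mbma_vpc`: `time_grid`, `bands` (data.frame
#'   `time`, `p2.5`, `p50`, `p97.5`), `bands_truncated`, `observed`,
#'   `coverage`, `n_sim`, `seed`.
#' @export
vpc <- function(fit, corpus, n_sim = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "mbma_fit"), n_sim >= 1L)
  prep <- .prep_fit(corpus, fit$model)
  params <- .normalize_params(.fit_params(fit), prep)
  info <- prep$info
  n_obs <- nrow(prep$obs)
  ord <- order(unlist(lapply(prep$blocks, `[[`, "idx")))
  se_w <- sqrt(unlist(lapply(prep$blocks, `[[`, "se2")))[ord]
  ## obs-level base parameter vectors, precomputed once; per replicate only
  ## the study multipliers exp(eta) and the residual draws change
  mult <- .cov_multipliers(prep$resolved, prep$arms,
                           as.list(params$theta[prep$resolved$theta_names]))
  fixed <- unlist(params$fixed)
  study_of <- match(prep$obs$study_id, prep$studies)
  base_obs <- local({
    out <- vector("list", length(prep$studies))
    for (si in seq_along(prep$studies))
      out[[si]] <- .base_params(prep$family, fixed, mult, prep$arms,
                                prep$blocks[[si]])
    idx <- unlist(lapply(prep$blocks, `[[`, "idx"))
    lapply(stats::setNames(names(out[[1L]]), names(out[[1L]])), function(nm)
      unlist(lapply(out, `[[`, nm))[order(idx)])
  })
  logt <- log(prep$obs$time)
  n_st <- length(prep$studies)
  sims <- with_seed(seed, {
    sapply(seq_len(n_sim), function(r) {
      eta <- matrix(stats::rnorm(n_st * length(info$re)), n_st,
                    length(info$re))
      eta <- sweep(eta, 2L, params$omega[info$re], `*`)
      pr <- if (prep$family == "lognormal") {
        mu_i <- base_obs$mu * exp(eta[study_of, 1L])
        sig_i <- base_obs$sigma * exp(eta[study_of, 2L])
        pnorm((logt - mu_i) / sig_i, lower.tail = FALSE)
      } else {
        exp(-base_obs$lambda0 * exp(eta[study_of, 1L]) * base_obs$g)
      }
      pr * (1 + se_w * stats::rnorm(n_obs, 0, params$eps[["prop"]])) +
        se_w * stats::rnorm(n_obs, 0, params$eps[["add"]])
    })
  })
  sims <- matrix(sims, nrow = n_obs)
  tg <- sort(unique(prep$obs$time))
  ## per observation slot (arm x time), quantiles across the replicates
  qs <- function(m) t(apply(m, 1L, stats::quantile,
                            probs = c(0.025, 0.5, 0.975), names = FALSE))
  b <- qs(sims)
  bt <- qs(pmin(pmax(sims, 0), 1))
  slot <- data.frame(study_id = prep$obs$study_id,
                     arm_id = prep$obs$arm_id, time = prep$obs$time,
                     stringsAsFactors = FALSE)
  bands <- cbind(slot, data.frame(p2.5 = b[, 1], p50 = b[, 2],
                                  p97.5 = b[, 3]))
  bands_tr <- cbind(slot, data.frame(p2.5 = bt[, 1], p50 = bt[, 2],
                                     p97.5 = bt[, 3]))
  inside <- prep$obs$obs_fraction >= bands$p2.5 &
    prep$obs$obs_fraction <= bands$p97.5
  structure(list(time_grid = tg, bands = bands,
                 bands_truncated = bands_tr,
                 observed = data.frame(study_id = prep$obs$study_id,
                                       arm_id = prep$obs$arm_id,
                                       time = prep$obs$time,
                                       obs_fraction = prep$obs$obs_fraction),
                 coverage = mean(inside), n_sim = n_sim, seed = seed),
            class = "mbma_vpc")
}

#' @export
print.mbma_vpc <- function(x, ...) {
  cat("<mbma_vpc>", x$n_sim, "replicates;",
      sprintf("95%%-band coverage of observations: %.1f%%\n",
              100 * x$coverage))
  invisible(x)
}

#' Study-level nonparametric bootstrap
#'
#' Resamples studies with replacement to the original study count (the study
#' is the resampling unit, preserving within-study correlation), refits each
#' replicate, and summarizes the converged replicates by parameter medians
#' and 2.5-97.5 percentile confidence intervals.
#'
#' @param corpus an `mbma_corpus`.
#' @param model an [mbma_model()].
#' @param n number of bootstrap replicates (default 1000).
#' @param seed integer seed; resampling and refits are reproducible.
#' @param init optional warm-start values passed to every refit (defaults
#'   to the full-data estimates).
#' @return an object of class `mbma_bootstrap`: `n_requested`,
#'   `n_converged`, `success_rate` (percent), `param_medians`, `ci95`
#'   (matrix with rows `lo`/`hi`), `estimates` (one row per converged
#'   replicate), `robust` (`FALSE` if fewer than half converged).
#' @export
bootstrap_model <- function(corpus, model, n = 1000L, seed = 1L,
                            init = NULL) {
  validate_corpus(corpus)
  studies <- unique(corpus$arms$study_id)
  if (length(studies) < 3L)
    stop_config("bootstrap_model: need >= 3 studies")
  if (is.null(init)) {
    full <- fit_mbma(corpus, model, seed = seed, compute_se = FALSE)
    init <- .fit_params(full)
  }
  draws <- with_seed(seed, {
    matrix(sample.int(length(studies), n * length(studies), replace = TRUE),
           nrow = n)
  })
  ests <- vector("list", n)
  for (b in seq_len(n)) {
    pick <- studies[draws[b, ]]
    arms <- do.call(rbind, lapply(seq_along(pick), function(j) {
      a <- corpus$arms[corpus$arms$study_id == pick[j], , drop = FALSE]
      a$study_id <- sprintf("B%02d_%s", j, pick[j])
      a
    }))
    obs <- do.call(rbind, lapply(seq_along(pick), function(j) {
      o <- corpus$obs[corpus$obs$study_id == pick[j],
                      setdiff(names(corpus$obs), "se"), drop = FALSE]
      o$study_id <- sprintf("B%02d_%s", j, pick[j])
      o
    }))
    bco <- mbma_corpus(arms, obs, meta = list(bootstrap_rep = b))
    f <- tryCatch(
      fit_mbma(bco, model, init = init, seed = seed, n_starts = 1L,
               compute_se = FALSE),
      error = function(e) NULL)
    if (!is.null(f) && f$converged)
      ests[[b]] <- c(f$theta,
                     stats::setNames(f$omega,
                                     paste0("omega_", names(f$omega))),
                     stats::setNames(f$eps, paste0("eps_", names(f$eps))))
  }
  ok <- !vapply(ests, is.null, TRUE)
  em <- do.call(rbind, ests[ok])
  structure(list(
    n_requested = n, n_converged = sum(ok),
    success_rate = 100 * sum(ok) / n,
    param_medians = if (sum(ok)) apply(em, 2, stats::median) else NULL,
    ci95 = if (sum(ok)) apply(em, 2, stats::quantile,
                              probs = c(0.025, 0.975)) else NULL,
    estimates = em, robust = sum(ok) >= n / 2, seed = seed),
    class = "mbma_bootstrap")
}

#' @export
print.mbma_bootstrap <- function(x, ...) {
  cat(sprintf("<mbma_bootstrap> %d/%d converged (%.1f%%)%s\n",
              x$n_converged, x$n_requested, x$success_rate,
              if (x$robust) "" else "  [WARNING: < 50% convergence]"))
  if (!is.null(x$param_medians)) {
    cat("  Parameter    median [95% CI]\n")
    for (nm in names(x$param_medians))
      cat(sprintf("  %-12s %8.4g [%.4g, %.4g]\n", nm, x$param_medians[nm],
                  x$ci95["2.5%", nm], x$ci95["97.5%", nm]))
  }
  invisible(x)
}

#' Sensitivity refit excluding flagged (open-label) arms
#'
#' Drops every arm whose flag column is `FALSE` (e.g. `blinded = FALSE`,
#' the open-label studies) and refits the same model, reporting the
#' estimates side by side with the full fit.
#'
#' @param corpus an `mbma_corpus`.
#' @param model an [mbma_model()].
#' @param exclude_flag name of a logical arm column; arms with value
#'   `FALSE` are excluded (default `"blinded"`).
#' @param full_fit optional full-data `mbma_fit` for the comparison column
#'   (fitted here if omitted).
#' @param seed integer seed.
#' @return list with `fit` (the sensitivity refit), `full_fit`,
#'   `comparison` (data.frame: parameter, full, sensitivity, ratio),
#'   `n_dropped_arms`.
#' @export
sensitivity_refit <- function(corpus, model, exclude_flag = "blinded",
                              full_fit = NULL, seed = 1L) {
  validate_corpus(corpus)
  flag <- corpus$arms[[exclude_flag]]
  if (is.null(flag))
    stop_config("sensitivity_refit: no arm column '", exclude_flag, "'")
  keep <- flag %in% TRUE
  if (!any(keep))
    stop_config("sensitivity_refit: all ", nrow(corpus$arms),
                " arms are flagged for exclusion")
  kept_studies <- unique(corpus$arms$study_id[keep])
  if (length(kept_studies) < 2L)
    stop_config("sensitivity_refit: only ", length(kept_studies),
                " study left after exclusion; need >= 2")
  arms <- corpus$arms[keep, , drop = FALSE]
  akey <- paste(arms$study_id, arms$arm_id)
  okey <- paste(corpus$obs$study_id, corpus$obs$arm_id)
  obs <- corpus$obs[okey %in% akey, setdiff(names(corpus$obs), "se"),
                    drop = FALSE]
  sub <- mbma_corpus(arms, obs, meta = corpus$meta)
  if (is.null(full_fit))
    full_fit <- fit_mbma(corpus, model, seed = seed, compute_se = FALSE)
  refit <- fit_mbma(sub, model, init = .fit_params(full_fit), seed = seed,
                    compute_se = FALSE)
  pname <- function(f) c(names(f$theta), paste0("omega_", names(f$omega)),
                         paste0("eps_", names(f$eps)))
  pval <- function(f) c(f$theta, f$omega, f$eps)
  comparison <- data.frame(parameter = pname(full_fit),
                           full = unname(pval(full_fit)),
                           sensitivity = unname(pval(refit)))
  comparison$ratio <- comparison$sensitivity / comparison$full
  list(fit = refit, full_fit = full_fit, comparison = comparison,
       n_dropped_arms = sum(!keep))
}
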