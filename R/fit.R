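## Hierarchical fit of parametric hazard models to arm-level survival
## fractions.
##
## Model: each study i carries a random effect vector eta_i ~ N(0, diag(omega^2))
## acting multiplicatively (P_i = P_pop * exp(eta_i)) on the family's
## variability-bearing parameters (mu and sigma for the log-normal family,
## lambda0 for the others). P_pop is the typical value scaled by the covariate
## engine. The observed fraction at time j is
##   Obs = Pred * (1 + SE * eps1) + SE * eps2,
## with eps1 ~ N(0, eps_prop^2), eps2 ~ N(0, eps_add^2) and SE the binomial
## standard error of the observed fraction, so the residual variance is
##   V = SE^2 * (Pred^2 * eps_prop^2 + eps_add^2).
## The marginal likelihood integrates eta_i per study; the integral is
## approximated by a Laplace expansion at the conditional mode (the open
## analogue of first-order conditional estimation), and the test suite bounds
## the approximation error against adaptive Gauss-Hermite quadrature.

#' Specify a hierarchical survival model
#'
#' @param family hazard family; see [hazard_params()].
#' @param covariates list of [covariate_effect()] declarations whose thetas
#'   are to be estimated (or, if `theta` is set, held fixed is not supported:
#'   supplied thetas are used as starting values).
#' @return an object of class `mbma_model`.
#' @export
mbma_model <- function(family = "lognormal", covariates = list()) {
  family <- match.arg(family, .hazard_families)
  if (inherits(covariates, "covariate_effect")) covariates <- list(covariates)
  structure(list(family = family, covariates = covariates),
            class = "mbma_model")
}

## fixed effects, their transforms and random-effect carriers per family
.family_info <- function(family) {
  switch(family,
    lognormal = list(
      fixed = c("mu", "sigma"), trans = c(mu = "id", sigma = "log"),
      lower = c(mu = 0.01, sigma = log(1e-3)),
      upper = c(mu = 10, sigma = log(50)),
      re = c("mu", "sigma")),
    exponential = list(
      fixed = "lambda0", trans = c(lambda0 = "log"),
      lower = c(lambda0 = log(1e-8)), upper = c(lambda0 = log(100)),
      re = "lambda0"),
    gompertz = list(
      fixed = c("lambda0", "beta"), trans = c(lambda0 = "log", beta = "id"),
      lower = c(lambda0 = log(1e-8), beta = -1),
      upper = c(lambda0 = log(100), beta = 1),
      re = "lambda0"),
    weibull_form = list(
      fixed = c("lambda0", "beta"), trans = c(lambda0 = "log", beta = "id"),
      lower = c(lambda0 = log(1e-8), beta = -0.99),
      upper = c(lambda0 = log(100), beta = 15),
      re = "lambda0"))
}

## Precompute per-study observation blocks. The weighting SE clamps the
## observed fraction to [0.5/n, 1 - 0.5/n] so boundary fractions (clipped
## digitization noise) keep a positive residual variance; the corpus `se`
## column itself is untouched.
.prep_fit <- function(corpus, model) {
  validate_corpus(corpus)
  arms <- corpus$arms
  obs <- corpus$obs
  resolved <- .resolve_effects(model$covariates, arms)
  key <- paste(arms$study_id, arms$arm_id)
  arm_idx <- match(paste(obs$study_id, obs$arm_id), key)
  n_of <- arms$n[arm_idx]
  p_cl <- pmin(pmax(obs$obs_fraction, 0.5 / n_of), 1 - 0.5 / n_of)
  se_w <- sqrt(p_cl * (1 - p_cl) / n_of)
  ## fractions exactly at 0 or 1 are boundary-censored: a Kaplan-Meier
  ## fraction hitting the physical bounds carries no usable binomial SE, so
  ## the likelihood treats the latent (pre-clipping) value as censored there
  cens <- ifelse(obs$obs_fraction >= 1, 1L,
                 ifelse(obs$obs_fraction <= 0, -1L, 0L))
  studies <- unique(arms$study_id)
  blocks <- lapply(studies, function(s) {
    i <- which(obs$study_id == s)
    list(t = obs$time[i], logt = log(obs$time[i]), obs = obs$obs_fraction[i],
         se2 = se_w[i]^2, n = n_of[i], cens = cens[i], arm = arm_idx[i],
         idx = i)
  })
  info <- .family_info(model$family)
  list(arms = arms, obs = obs, resolved = resolved, studies = studies,
       blocks = blocks, info = info, family = model$family)
}

## negative penalized log-likelihood and its analytic eta-gradient for one
## study; `base` holds obs-level base parameter vectors, `act` the indices of
## random effects being integrated (omega > 0).
## Assemble the per-study data bundle consumed by the top-level inner
## functions below. These are deliberately plain functions of (eta, d) --
## not closures -- so R byte-compiles them once at install time instead of
## re-compiling a fresh closure on every objective evaluation.
.study_dat <- function(family, blk, base, ep2, ea2, om_act, act) {
  int <- which(blk$cens == 0L)
  cns <- which(blk$cens != 0L)
  list(family = family, blk = blk, base = base, ep2 = ep2, ea2 = ea2,
       om_act = om_act, act = act, int = int, cns = cns,
       k = length(act$which))
}

.surv_at <- function(eta, d, sel) {
  full <- numeric(length(d$act$all))
  full[d$act$which] <- eta
  if (d$family == "lognormal") {
    mu_i <- d$base$mu[sel] * exp(full[1L])
    sig_i <- d$base$sigma[sel] * exp(full[2L])
    pnorm((d$blk$logt[sel] - mu_i) / sig_i, lower.tail = FALSE)
  } else {
    exp(-d$base$lambda0[sel] * exp(full[1L]) * d$base$g[sel])
  }
}

.score_core <- function(eta, d) {
  full <- numeric(length(d$act$all))
  full[d$act$which] <- eta
  int <- d$int
  if (d$family == "lognormal") {
    mu_i <- d$base$mu[int] * exp(full[1L])
    sig_i <- d$base$sigma[int] * exp(full[2L])
    z <- (d$blk$logt[int] - mu_i) / sig_i
    S <- pnorm(z, lower.tail = FALSE)
    phi <- dnorm(z)
    dS <- cbind(phi * mu_i / sig_i, phi * z)[, d$act$which, drop = FALSE]
  } else {
    lam <- d$base$lambda0[int] * exp(full[1L])
    Lam <- lam * d$base$g[int]
    S <- exp(-Lam)
    dS <- cbind(-S * Lam)[, d$act$which, drop = FALSE]
  }
  V <- d$blk$se2[int] * (S * S * d$ep2 + d$ea2)
  list(S = S, dS = dS, V = V, r = d$blk$obs[int] - S)
}

## boundary-censored contribution: the latent (pre-clip) value lies beyond
## the bound; the weighting SE comes from the model prediction because the
## observed fraction is degenerate there
.cens_nll <- function(eta, d) {
  cns <- d$cns
  Sc <- pmin(pmax(.surv_at(eta, d, cns), 1e-12), 1 - 1e-12)
  v <- (Sc * (1 - Sc) / d$blk$n[cns]) * (Sc * Sc * d$ep2 + d$ea2)
  sdv <- sqrt(pmax(v, 1e-300))
  up <- d$blk$cens[cns] == 1L
  ll <- numeric(length(cns))
  ll[up] <- pnorm((1 - Sc[up]) / sdv[up], lower.tail = FALSE, log.p = TRUE)
  ll[!up] <- pnorm(-Sc[!up] / sdv[!up], log.p = TRUE)
  -sum(ll)
}

.study_npll <- function(eta, d) {
  cv <- .score_core(eta, d)
  out <- 0.5 * sum(log(2 * pi * cv$V) + cv$r^2 / cv$V) +
    0.5 * sum(log(2 * pi * d$om_act^2) + eta^2 / d$om_act^2)
  if (length(d$cns)) out <- out + .cens_nll(eta, d)
  out
}

.study_grad <- function(eta, d, gn_hess = FALSE) {
  cv <- .score_core(eta, d)
  ## d npll / d S per observation, including the variance interaction term
  dVdS <- 2 * d$blk$se2[d$int] * cv$S * d$ep2
  coef <- (0.5 / cv$V - 0.5 * cv$r^2 / cv$V^2) * dVdS - cv$r / cv$V
  g <- as.numeric(crossprod(cv$dS, coef)) + eta / d$om_act^2
  if (length(d$cns)) {
    ## censored part: central differences on the few censored points
    h <- 1e-6
    for (j in seq_along(g)) {
      ep_ <- em_ <- eta
      ep_[j] <- ep_[j] + h; em_[j] <- em_[j] - h
      g[j] <- g[j] + (.cens_nll(ep_, d) - .cens_nll(em_, d)) / (2 * h)
    }
  }
  if (!gn_hess) return(g)
  ## Gauss-Newton curvature from the same pass: positive definite, used
  ## only to propose Newton steps (the Laplace determinant uses the exact
  ## finite-difference Hessian at the mode)
  w <- 1 / cv$V + dVdS^2 / (2 * cv$V^2)
  H <- crossprod(cv$dS, cv$dS * w) + diag(1 / d$om_act^2, d$k)
  list(g = g, H = H)
}

.study_fd_hess <- function(eta, d) {
  k <- d$k
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-4 * (1 + abs(eta[j]))
    ep <- em <- eta
    ep[j] <- ep[j] + h; em[j] <- em[j] - h
    H[, j] <- (.study_grad(ep, d) - .study_grad(em, d)) / (2 * h)
  }
  (H + t(H)) / 2
}

## Laplace contribution of one study: -2 log integral ~=
## 2 * npll(mode) - k log(2 pi) + log det H(mode).
## Conditional-mode search: damped Newton from eta = 0 with analytic
## gradient and finite-difference Hessian of the gradient. Starting from a
## fixed point keeps the Laplace value a pure function of the outer
## parameters (no path dependence for the outer optimizer to trip on).
.study_laplace <- function(d) {
  k <- d$k
  eta_hat <- numeric(k)
  f_cur <- .study_npll(eta_hat, d)
  for (it in 1:40) {
    gh <- .study_grad(eta_hat, d, gn_hess = TRUE)
    g <- gh$g
    if (sqrt(sum(g^2)) < 1e-9) break
    step <- tryCatch(-solve(gh$H, g), error = function(e) NULL)
    if (is.null(step) || sum(step * g) > 0)
      step <- -g / max(sqrt(sum(g^2)), 1)  # fall back to steepest descent
    if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))
    ok <- FALSE
    for (hv in 1:8) {
      cand <- eta_hat + step
      f_new <- .study_npll(cand, d)
      if (is.finite(f_new) && f_new <= f_cur - 1e-14 * abs(f_cur)) {
        ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok) break
    eta_hat <- cand
    f_cur <- f_new
  }
  H <- .study_fd_hess(eta_hat, d)
  dt <- if (k == 1L) H[1L, 1L] else H[1L, 1L] * H[2L, 2L] - H[1L, 2L]^2
  if (!is.finite(dt) || dt <= 0) {
    H <- H + diag(max(abs(diag(H))) * 1e-6 + 1e-8, k)
    dt <- if (k == 1L) H[1L, 1L] else H[1L, 1L] * H[2L, 2L] - H[1L, 2L]^2
    if (!is.finite(dt) || dt <= 0) return(list(ofv = 1e8, eta = eta_hat,
                                               var = rep(NA_real_, k)))
  }
  cv <- tryCatch(diag(solve(H)), error = function(e) rep(NA_real_, k))
  list(ofv = 2 * f_cur - k * log(2 * pi) + log(dt),
       eta = eta_hat, var = cv)
}

## obs-level base parameters per study block, after covariate scaling
.base_params <- function(family, fixed, mult, arms, blk) {
  a <- blk$arm
  if (family == "lognormal") {
    mu_a <- fixed[["mu"]] * (mult$mu %||% rep(1, nrow(arms)))
    sg_a <- fixed[["sigma"]] * (mult$sigma %||% rep(1, nrow(arms)))
    if (any(mu_a <= 0) || any(sg_a <= 0)) return(NULL)
    list(mu = mu_a[a], sigma = sg_a[a])
  } else {
    la <- fixed[["lambda0"]] * (mult$lambda0 %||% rep(1, nrow(arms)))
    if (any(la <= 0)) return(NULL)
    g <- switch(family,
      exponential  = blk$t,
      gompertz     = {
        b <- fixed[["beta"]]
        if (abs(b) < 1e-8) blk$t * (1 + b * blk$t / 2)
        else expm1(b * blk$t) / b
      },
      weibull_form = blk$t^(fixed[["beta"]] + 1) / (fixed[["beta"]] + 1))
    list(lambda0 = la[a], g = g)
  }
}

## Core objective: -2 log marginal likelihood for natural-scale parameters.
.ofv_impl <- function(prep, params, want_ebe = FALSE) {
  info <- prep$info
  fixed <- params$fixed
  omega <- params$omega
  eps <- params$eps
  if (any(!is.finite(unlist(params[c("fixed", "theta", "omega", "eps")]))))
    return(if (want_ebe) list(ofv = 1e10) else 1e10)
  mult <- tryCatch(
    .cov_multipliers(prep$resolved, prep$arms,
                     as.list(params$theta[prep$resolved$theta_names])),
    error = function(e) NULL)
  if (is.null(mult) && length(prep$resolved$theta_names) > 0)
    return(if (want_ebe) list(ofv = 1e10) else 1e10)
  if (is.null(mult)) mult <- list()
  act_which <- which(omega[info$re] > 0)
  k <- length(act_which)
  act <- list(all = info$re, which = act_which)
  om_act <- omega[info$re][act_which]
  ep2 <- eps[["prop"]]^2
  ea2 <- eps[["add"]]^2
  total <- 0
  ebe <- matrix(0, length(prep$studies), length(info$re),
                dimnames = list(prep$studies, info$re))
  evar <- ebe
  for (si in seq_along(prep$studies)) {
    blk <- prep$blocks[[si]]
    base <- .base_params(prep$family, fixed, mult, prep$arms, blk)
    if (is.null(base)) return(if (want_ebe) list(ofv = 1e10) else 1e10)
    d <- .study_dat(prep$family, blk, base, ep2, ea2, om_act, act)
    if (k == 0L) {
      contrib <- 2 * .study_npll(numeric(0), d)
    } else {
      ## inner solves always start from zero: the Laplace value must be a
      ## pure function of the outer parameters for the outer optimizer
      lap <- .study_laplace(d)
      contrib <- lap$ofv
      if (want_ebe) {
        ebe[si, act_which] <- lap$eta
        evar[si, act_which] <- lap$var
      }
    }
    if (!is.finite(contrib)) return(if (want_ebe) list(ofv = 1e10) else 1e10)
    total <- total + contrib
  }
  if (want_ebe) list(ofv = total, ebe = ebe, ebe_var = evar) else total
}

## natural <-> transformed packing -------------------------------------------

.pack_layout <- function(prep) {
  info <- prep$info
  tn <- prep$resolved$theta_names
  list(
    names = c(info$fixed, tn, paste0("log_omega_", info$re),
              "log_eps_prop", "log_eps_add"),
    n_fixed = length(info$fixed), theta_names = tn, re = info$re)
}

.to_trans <- function(params, prep) {
  info <- prep$info
  f <- vapply(info$fixed, function(nm)
    if (info$trans[[nm]] == "log") log(params$fixed[[nm]])
    else params$fixed[[nm]], 0)
  th <- if (length(prep$resolved$theta_names))
    unname(unlist(params$theta[prep$resolved$theta_names])) else numeric(0)
  c(f, th, log(pmax(params$omega[info$re], 1e-300)),
    log(pmax(params$eps[c("prop", "add")], 1e-300)))
}

.from_trans <- function(p, prep) {
  info <- prep$info
  nf <- length(info$fixed)
  fixed <- stats::setNames(p[seq_len(nf)], info$fixed)
  for (nm in info$fixed)
    if (info$trans[[nm]] == "log") fixed[[nm]] <- exp(fixed[[nm]])
  tn <- prep$resolved$theta_names
  nt <- length(tn)
  theta <- stats::setNames(as.list(p[nf + seq_len(nt)]), tn)
  nr <- length(info$re)
  omega <- stats::setNames(exp(p[nf + nt + seq_len(nr)]), info$re)
  eps <- stats::setNames(exp(p[nf + nt + nr + 1:2]), c("prop", "add"))
  list(fixed = fixed, theta = theta, omega = omega, eps = eps)
}

.trans_bounds <- function(prep) {
  info <- prep$info
  tn <- prep$resolved$theta_names
  cat_terms <- vapply(prep$resolved$terms, function(tm)
    tm$kind == "categorical", TRUE)
  th_lo <- th_hi <- numeric(0)
  for (tm in prep$resolved$terms) {
    n_th <- length(tm$theta_names)
    if (tm$kind == "categorical") {
      th_lo <- c(th_lo, rep(-0.99, n_th)); th_hi <- c(th_hi, rep(20, n_th))
    } else {
      th_lo <- c(th_lo, rep(-50, n_th)); th_hi <- c(th_hi, rep(50, n_th))
    }
  }
  list(lower = c(info$lower[info$fixed], th_lo,
                 rep(log(1e-6), length(info$re)), rep(log(1e-6), 2)),
       upper = c(info$upper[info$fixed], th_hi,
                 rep(log(5), length(info$re)), rep(log(100), 2)))
}

#' Marginal objective function value (-2 log marginal likelihood)
#'
#' Evaluates the Laplace-approximated marginal likelihood of a parameter set
#' on a corpus. Random effects whose `omega` is exactly zero are fixed at
#' zero and excluded from the Laplace expansion, so with all omegas zero the
#' value is the closed-form weighted Gaussian -2 log-likelihood.
#'
#' @param corpus an `mbma_corpus`.
#' @param model an [mbma_model()].
#' @param params list with elements `fixed` (named, natural scale), `theta`
#'   (named covariate scaling factors, may be empty), `omega` (named by the
#'   family's random-effect carriers), `eps` (named `prop`, `add`).
#' @param ebe if `TRUE`, attach per-study conditional modes (`"ebe"`) and
#'   conditional variances (`"ebe_var"`) as attributes.
#' @return the objective function value (scalar).
#' @export
marginal_ofv <- function(corpus, model, params, ebe = FALSE) {
  prep <- .prep_fit(corpus, model)
  params <- .normalize_params(params, prep)
  if (ebe) {
    r <- .ofv_impl(prep, params, want_ebe = TRUE)
    structure(r$ofv, ebe = r$ebe, ebe_var = r$ebe_var)
  } else {
    .ofv_impl(prep, params)
  }
}

.normalize_params <- function(params, prep) {
  info <- prep$info
  fixed <- unlist(params$fixed)[info$fixed]
  if (anyNA(fixed))
    stop_config("params$fixed must supply ", paste(info$fixed, collapse = ", "))
  omega <- stats::setNames(rep(0, length(info$re)), info$re)
  if (!is.null(params$omega)) {
    ov <- unlist(params$omega)
    omega[intersect(names(ov), info$re)] <-
      ov[intersect(names(ov), info$re)]
  }
  eps <- unlist(params$eps)[c("prop", "add")]
  if (anyNA(eps)) stop_config("params$eps must supply prop and add")
  if (all(eps == 0)) stop_config("at least one residual component must be > 0")
  theta <- as.list(params$theta %||% list())
  if (length(miss <- setdiff(prep$resolved$theta_names, names(theta))))
    stop_config("params$theta lacks ", paste(miss, collapse = ", "))
  list(fixed = as.list(fixed), theta = theta, omega = omega, eps = eps)
}

## crude per-arm median-crossing guess used to start the optimizer
.median_guess <- function(corpus) {
  key <- paste(corpus$obs$study_id, corpus$obs$arm_id)
  meds <- vapply(unique(key), function(k) {
    i <- key == k
    tt <- corpus$obs$time[i]; p <- corpus$obs$obs_fraction[i]
    j <- which(p <= 0.5)[1L]
    if (!is.na(j)) {
      if (j == 1L) tt[1L]
      else tt[j - 1L] + (tt[j] - tt[j - 1L]) * (p[j - 1L] - 0.5) /
        max(p[j - 1L] - p[j], 1e-9)
    } else {
      tail_p <- max(min(p[length(p)], 0.999), 1e-3)
      tt[length(tt)] * log(2) / max(-log(tail_p), 0.05)
    }
  }, 0)
  stats::median(meds)
}

.default_init <- function(corpus, prep) {
  med <- max(.median_guess(corpus), 0.5)
  fixed <- switch(prep$family,
    lognormal    = list(mu = log(med), sigma = 1),
    exponential  = list(lambda0 = log(2) / med),
    gompertz     = list(lambda0 = log(2) / med, beta = 0),
    weibull_form = list(lambda0 = log(2) / med, beta = 0))
  theta <- stats::setNames(as.list(rep(0, length(prep$resolved$theta_names))),
                           prep$resolved$theta_names)
  ## start thetas at declared values when the model supplies them
  for (tm in prep$resolved$terms)
    if (!is.null(tm$theta)) theta[tm$theta_names] <- as.list(tm$theta)
  list(fixed = fixed, theta = theta,
       omega = stats::setNames(rep(0.1, length(prep$info$re)), prep$info$re),
       eps = c(prop = 0.5, add = 1))
}

#' Fit the hierarchical survival model
#'
#' Minimizes the Laplace marginal OFV over transformed parameters (log scale
#' for the scale, variability and residual components). The optimizer runs
#' from a data-driven start and, if that start fails to converge, from up to
#' `n_starts - 1` seeded jittered restarts.
#'
#' @param corpus an `mbma_corpus` with at least two studies.
#' @param model an [mbma_model()].
#' @param init optional partial list of starting values (`fixed`, `theta`,
#'   `omega`, `eps`), merged over the data-driven defaults.
#' @param seed integer seed controlling the restart jitter.
#' @param n_starts maximum number of optimizer starts.
#' @param compute_se if `TRUE`, derive relative standard errors from a
#'   central-difference Hessian of the marginal OFV (adds a few seconds).
#' @param control optional overrides for [stats::nlminb()] control.
#' @return an object of class `mbma_fit` with elements `theta` (fixed
#'   effects and covariate scaling factors, natural scale), `omega`
#'   (between-study SDs), `eps` (residual SDs `prop` and `add`), `ofv`,
#'   `se_pct`, `ebe` (per-study conditional modes), `ebe_var`, `converged`,
#'   `effects` (covariate effects with estimated thetas filled in).
#' @export
fit_mbma <- function(corpus, model, init = NULL, seed = 1L, n_starts = 3L,
                     compute_se = TRUE, control = list()) {
  prep <- .prep_fit(corpus, model)
  if (length(prep$studies) < 2L)
    stop_config("fit_mbma: need >= 2 studies to estimate between-study ",
                "variability")
  start <- .default_init(corpus, prep)
  for (nm in names(init %||% list()))
    start[[nm]] <- utils::modifyList(as.list(start[[nm]]), as.list(init[[nm]]))
  start$omega <- unlist(start$omega)[prep$info$re]
  start$eps <- unlist(start$eps)[c("prop", "add")]
  p0 <- .to_trans(start, prep)
  bounds <- .trans_bounds(prep)
  p0 <- pmin(pmax(p0, bounds$lower + 1e-9), bounds$upper - 1e-9)
  ctl <- utils::modifyList(
    list(rel.tol = 1e-8, iter.max = 400, eval.max = 900), control)
  obj <- function(p) .ofv_impl(prep, .from_trans(p, prep))
  run_one <- function(ps) {
    res <- tryCatch(
      stats::nlminb(ps, obj, lower = bounds$lower, upper = bounds$upper,
                    control = ctl),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = ps))
    if (res$convergence != 0L && is.finite(res$objective)) {
      ## a flat profile (the proportional residual SD can be barely
      ## identified) often triggers "false convergence"; a restart that
      ## fails to improve the OFV confirms a restart-stable optimum
      res2 <- tryCatch(
        stats::nlminb(res$par, obj, lower = bounds$lower,
                      upper = bounds$upper, control = ctl),
        error = function(e) NULL)
      if (!is.null(res2) && is.finite(res2$objective)) {
        if (res$objective - res2$objective < 1e-3) {
          res2$convergence <- 0L
          res2$message <- paste0("restart-stable (", res2$message, ")")
        }
        if (res2$objective <= res$objective) res <- res2
      }
    }
    res
  }
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    ps <- if (s == 1L) p0 else with_seed(seed * 1000L + s, {
      pmin(pmax(p0 + stats::rnorm(length(p0), 0, 0.3),
                bounds$lower + 1e-9), bounds$upper - 1e-9)
    })
    res <- run_one(ps)
    res$start <- s
    if (is.null(best) || (res$objective < best$objective - 1e-9) ||
        (res$convergence == 0L && best$convergence != 0L &&
         res$objective < best$objective + 1e-6))
      best <- res
    if (best$convergence == 0L && is.finite(best$objective)) break
  }
  est <- .from_trans(best$par, prep)
  fin <- .ofv_impl(prep, est, want_ebe = TRUE)
  layout <- .pack_layout(prep)
  theta_nat <- c(unlist(est$fixed), unlist(est$theta))
  se_pct <- stats::setNames(rep(NA_real_, length(layout$names)),
                            layout$names)
  vcov_t <- NULL
  if (compute_se && best$convergence == 0L) {
    H <- tryCatch(pracma::hessian(obj, best$par), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_t <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
      if (!is.null(vcov_t)) {
        se_t <- sqrt(pmax(diag(vcov_t), 0))
        nat <- c(theta_nat, est$omega, est$eps)
        is_log <- c(prep$info$trans[prep$info$fixed] == "log",
                    rep(FALSE, length(layout$theta_names)),
                    rep(TRUE, length(prep$info$re) + 2L))
        se_nat <- ifelse(is_log, se_t * abs(nat), se_t)
        se_pct <- 100 * se_nat / pmax(abs(nat), 1e-300)
        names(se_pct) <- layout$names
      }
    }
  }
  effects_hat <- .effects_with_theta(prep$resolved, est$theta)
  structure(list(
    family = prep$family,
    model = mbma_model(prep$family, effects_hat),
    theta = theta_nat,
    omega = est$omega,
    eps = est$eps,
    ofv = if (is.finite(fin$ofv)) fin$ofv else best$objective,
    se_pct = se_pct,
    vcov_trans = vcov_t,
    param_names = layout$names,
    ebe = fin$ebe,
    ebe_var = fin$ebe_var,
    effects = effects_hat,
    converged = best$convergence == 0L && is.finite(best$objective),
    message = best$message %||% "",
    start_used = best$start,
    n_studies = length(prep$studies),
    n_obs = nrow(prep$obs),
    studies = prep$studies,
    seed = seed), class = "mbma_fit")
}

## rebuild covariate_effect objects with estimated thetas filled in
.effects_with_theta <- function(resolved, theta) {
  lapply(resolved$terms, function(tm) {
    if (tm$kind == "continuous")
      covariate_effect(tm$covariate, target = tm$target, kind = "continuous",
                       theta = theta[[tm$theta_names]],
                       cov_median = tm$cov_median)
    else
      covariate_effect(tm$covariate, target = tm$target, kind = "categorical",
                       theta = stats::setNames(
                         vapply(tm$theta_names, function(nm) theta[[nm]], 0),
                         tm$levels),
                       reference = tm$reference)
  })
}

#' @export
print.mbma_fit <- function(x, ...) {
  cat("<mbma_fit> family =", x$family,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  OFV: %.3f over %d studies / %d observations\n",
              x$ofv, x$n_studies, x$n_obs))
  est <- c(x$theta, stats::setNames(x$omega, paste0("omega_", names(x$omega))),
           stats::setNames(x$eps, paste0("eps_", names(x$eps))))
  se <- x$se_pct
  cat("  Parameter  Estimate (SE%)\n")
  for (i in seq_along(est))
    cat(sprintf("  %-12s %9.4g (%s)\n", names(est)[i], est[i],
                if (is.finite(se[i])) sprintf("%.1f", se[i]) else "-"))
  invisible(x)
}

#' Per-study empirical Bayes estimates
#'
#' Conditional modes of each study's random effects given its data and the
#' fitted population parameters; estimates shrink toward zero as the study
#' information or `omega` decreases.
#'
#' @param fit an `mbma_fit`.
#' @param corpus optional corpus on which to recompute the conditional
#'   modes; defaults to the estimates stored at fit time.
#' @return matrix of eta estimates, studies x random effects.
#' @export
empirical_bayes <- function(fit, corpus = NULL) {
  stopifnot(inherits(fit, "mbma_fit"))
  if (is.null(corpus)) return(fit$ebe)
  o <- marginal_ofv(corpus, fit$model, .fit_params(fit), ebe = TRUE)
  attr(o, "ebe")
}

## parameter list (natural scale) of a fit, in marginal_ofv() form
.fit_params <- function(fit) {
  info <- .family_info(fit$family)
  list(fixed = as.list(fit$theta[info$fixed]),
       theta = as.list(fit$theta[setdiff(names(fit$theta), info$fixed)]),
       omega = fit$omega, eps = fit$eps)
}

#' Predicted survival fractions for one arm
#'
#' Applies the covariate engine and the multiplicative study effect
#' (`P_i = P_pop * exp(eta)`) to the fitted (or supplied) population
#' parameters and evaluates the survival function.
#'
#' @param fit an `mbma_fit` (or a list with `family`, `theta`, `effects`).
#' @param profile named list / one-row data.frame of covariate values.
#' @param times months, strictly positive.
#' @param eta named numeric of study effects (defaults to zero: population
#'   prediction).
#' @return predicted fractions in `(0, 1]`.
#' @export
arm_prediction <- function(fit, profile, times, eta = NULL) {
  if (any(times <= 0)) stop("arm_prediction: times must be > 0", call. = FALSE)
  info <- .family_info(fit$family)
  eta_full <- stats::setNames(rep(0, length(info$re)), info$re)
  if (!is.null(eta)) {
    eta <- unlist(eta)
    if (is.null(names(eta)) && length(eta) == length(info$re))
      names(eta) <- info$re
    eta_full[intersect(names(eta), info$re)] <-
      eta[intersect(names(eta), info$re)]
  }
  pv <- list()
  for (nm in info$fixed) {
    eff <- Filter(function(e) e$target == nm, fit$effects %||% list())
    val <- apply_covariate(fit$theta[[nm]], profile, eff)
    if (nm %in% info$re) val <- val * exp(eta_full[[nm]])
    pv[[nm]] <- val
  }
  hp <- do.call(hazard_params, c(list(family = fit$family), pv))
  surv_prob(hp, times)
}
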