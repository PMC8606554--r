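# Shared fixtures and independent oracles for the test suite.

# -- corpus builders ---------------------------------------------------------

# minimal valid arms row
arm_row <- function(study_id = "S1", arm_id = "A1", n = 100L,
                    therapy_type = "monotherapy", drug = "olaparib",
                    biomarker = "BRCAm", platinum = "sensitive",
                    partner = "none", ...) {
  data.frame(study_id = study_id, arm_id = arm_id, n = n,
             therapy_type = therapy_type, drug = drug, biomarker = biomarker,
             platinum = platinum, partner = partner, ...,
             stringsAsFactors = FALSE)
}

# small corpus: survival fractions exactly on a log-normal curve, one arm
# per study, no noise
exact_lognormal_corpus <- function(n_studies = 3, mu = 2.5, sigma = 1,
                                   times = c(3, 6, 12, 24), n = 200L) {
  hp <- hazard_params("lognormal", mu = mu, sigma = sigma)
  arms <- do.call(rbind, lapply(seq_len(n_studies), function(i)
    arm_row(study_id = paste0("S", i), n = n)))
  obs <- do.call(rbind, lapply(seq_len(n_studies), function(i)
    data.frame(study_id = paste0("S", i), arm_id = "A1", time = times,
               obs_fraction = surv_prob(hp, times),
               stringsAsFactors = FALSE)))
  mbma_corpus(arms, obs)
}

# random valid corpus for property tests (round-trips etc.)
random_corpus <- function(seed) {
  set.seed(seed)
  n_stud <- sample(2:4, 1)
  arms <- do.call(rbind, lapply(seq_len(n_stud), function(i) {
    n_arm <- sample(1:2, 1)
    do.call(rbind, lapply(seq_len(n_arm), function(j) {
      tt <- sample(c("monotherapy", "combination"), 1)
      arm_row(study_id = paste0("S", i), arm_id = paste0("A", j),
              n = sample(20:300, 1), therapy_type = tt,
              drug = sample(c("olaparib", "niraparib", "rucaparib"), 1),
              biomarker = sample(c("BRCAm", "BRCAwt", "HRD_positive"), 1),
              platinum = sample(c("sensitive", "partially_resistant"), 1),
              partner = if (tt == "monotherapy") "none" else
                sample(c("chemotherapy", "bevacizumab", "cediranib"), 1),
              ecog0_pct = round(runif(1, 40, 90), 1),
              median_age = round(runif(1, 50, 70), 1),
              blinded = sample(c(TRUE, FALSE), 1))
    }))
  }))
  obs <- do.call(rbind, lapply(seq_len(nrow(arms)), function(a) {
    tt <- sort(sample(seq(2, 36, by = 2), sample(3:8, 1)))
    data.frame(study_id = arms$study_id[a], arm_id = arms$arm_id[a],
               time = tt, obs_fraction = round(runif(length(tt)), 4),
               stringsAsFactors = FALSE)
  }))
  mbma_corpus(arms, obs)
}

# published_model/published_truth_params: the final log-normal model and its
# reported parameter values, shared across test files.

# -- shared fitted model (computed once per test run) ------------------------

.fixture_env <- new.env(parent = emptyenv())

published_model <- function() {
  mbma_model("lognormal", list(
    covariate_effect("therapy_type", target = "mu", kind = "categorical",
                     reference = "combination")))
}

published_truth_params <- function() {
  list(fixed = list(mu = 2.96, sigma = 0.999),
       theta = list(therapy_type = -0.215),
       omega = c(mu = 0.159, sigma = 0.142),
       eps = c(prop = 0.429, add = 1.241))
}

shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    co <- generate_corpus(parp_design(), seed = 1)
    .fixture_env$corpus <- co
    .fixture_env$fit <- fit_mbma(co, published_model(), seed = 1,
                                 compute_se = FALSE)
  }
  list(fit = .fixture_env$fit, corpus = .fixture_env$corpus)
}

# -- independent oracles -----------------------------------------------------

# survival by adaptive quadrature of the hazard (oracle for the closed forms)
surv_by_quadrature <- function(params, t) {
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    exp(-stats::integrate(function(u) hazard_rate(params, u), 0, tt,
                          rel.tol = 1e-12, abs.tol = 1e-14)$value)
  }, 0)
}

# textbook DerSimonian-Laird pooling (oracle for random_effects_pool)
dl_pool_oracle <- function(y, se, level = 90) {
  w <- 1 / se^2
  yf <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yf)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(y) - 1)) / C)
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * y) / sum(ws)
  sep <- sqrt(1 / sum(ws))
  z <- qnorm((1 + level / 100) / 2)
  list(pooled = pooled, se = sep, tau2 = tau2,
       ci = c(pooled - z * sep, pooled + z * sep))
}

# -2 log marginal likelihood by adaptive Gauss-Hermite quadrature (oracle
# for the Laplace approximation); corpus must have no boundary fractions
gh_ofv_oracle <- function(corpus, model, params, n_nodes = 9) {
  gh <- pracma::gaussHermite(n_nodes)
  prep <- survmbma:::.prep_fit(corpus, model)
  params <- survmbma:::.normalize_params(params, prep)
  info <- prep$info
  mult <- survmbma:::.cov_multipliers(
    prep$resolved, prep$arms,
    as.list(params$theta[prep$resolved$theta_names]))
  act_which <- which(params$omega[info$re] > 0)
  k <- length(act_which)
  om_act <- params$omega[info$re][act_which]
  total <- 0
  for (si in seq_along(prep$studies)) {
    blk <- prep$blocks[[si]]
    base <- survmbma:::.base_params(prep$family, unlist(params$fixed), mult,
                                    prep$arms, blk)
    d <- survmbma:::.study_dat(prep$family, blk, base,
                               params$eps[["prop"]]^2,
                               params$eps[["add"]]^2, om_act,
                               list(all = info$re, which = act_which))
    if (k == 0) {
      total <- total + 2 * survmbma:::.study_npll(numeric(0), d)
      next
    }
    # center and scale at the conditional mode (adaptive GH)
    lap <- survmbma:::.study_laplace(d)
    m <- lap$eta
    H <- survmbma:::.study_fd_hess(m, d)
    L <- t(chol(solve(H)))
    if (k == 1) {
      nodes <- matrix(gh$x, ncol = 1)
      wts <- gh$w
    } else {
      nodes <- as.matrix(expand.grid(gh$x, gh$x))
      wts <- as.vector(outer(gh$w, gh$w))
    }
    vals <- vapply(seq_len(nrow(nodes)), function(j) {
      z <- nodes[j, ]
      eta <- as.numeric(m + sqrt(2) * L %*% z)
      -survmbma:::.study_npll(eta, d) + sum(z^2)
    }, 0)
    mx <- max(vals)
    log_integral <- (k / 2) * log(2) + log(det(L)) + mx +
      log(sum(wts * exp(vals - mx)))
    total <- total - 2 * log_integral
  }
  total
}
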