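## Covariate parameterization and missingness handling.
##
## Categorical covariates scale a typical parameter value multiplicatively,
## P_pop = P_typical * (1 + theta) off the reference level; continuous
## covariates act through P_pop = P_typical * exp((x - x_median) * theta),
## centred at the n-weighted corpus median so the typical value is the value
## at the median covariate. Multiple effects compose multiplicatively.

#' Declare a covariate effect
#'
#' @param covariate arm-level column name (e.g. `"therapy_type"`).
#' @param target name of the fixed effect it scales (default `"mu"`, the
#'   log-normal log-time location; `"lambda0"` for the other families).
#' @param kind `"categorical"` or `"continuous"`. If omitted it is inferred
#'   from the corpus column type at resolution time.
#' @param theta scaling factor(s). For a categorical covariate, a named
#'   vector with one entry per non-reference level (each > -1); for a
#'   continuous covariate a scalar. Leave `NULL` for effects whose theta is
#'   to be estimated.
#' @param reference reference level (categorical). Defaults per covariate:
#'   combination (therapy_type), none (partner), sensitive (platinum),
#'   olaparib (drug), BRCAm (biomarker); otherwise the most common level by
#'   patient count.
#' @param cov_median centring value (continuous); defaults to the n-weighted
#'   corpus median.
#' @return an object of class `covariate_effect`.
#' @export
covariate_effect <- function(covariate, target = "mu", kind = NULL,
                             theta = NULL, reference = NULL,
                             cov_median = NULL) {
  stopifnot(is.character(covariate), length(covariate) == 1L)
  if (!is.null(kind)) kind <- match.arg(kind, c("categorical", "continuous"))
  structure(list(covariate = covariate, target = target, kind = kind,
                 theta = theta, reference = reference,
                 cov_median = cov_median),
            class = "covariate_effect")
}

.default_reference <- c(therapy_type = "combination", partner = "none",
                        platinum = "sensitive", drug = "olaparib",
                        biomarker = "BRCAm")

## Resolve declared effects against the arms table: infer kind, reference,
## non-reference levels, centring medians, and lay out the theta vector.
.resolve_effects <- function(effects, arms) {
  terms <- list()
  theta_names <- character(0)
  for (e in effects) {
    stopifnot(inherits(e, "covariate_effect"))
    if (!e$covariate %in% names(arms))
      stop_config("covariate '", e$covariate, "' not found in arms table")
    v <- arms[[e$covariate]]
    kind <- e$kind %||% if (is.numeric(v)) "continuous" else "categorical"
    if (kind == "continuous") {
      if (!is.numeric(v))
        stop_config("covariate '", e$covariate, "' is not numeric")
      if (anyNA(v))
        stop_config("covariate '", e$covariate, "' has missing values; ",
                    "impute_missing() first")
      med <- e$cov_median %||% weighted_median(v, arms$n)
      nm <- e$covariate
      tm <- list(covariate = e$covariate, target = e$target, kind = kind,
                 cov_median = med, theta_names = nm, theta = e$theta)
    } else {
      v <- as.character(v)
      if (anyNA(v))
        stop_config("covariate '", e$covariate, "' has missing values")
      ref <- e$reference %||%
        unname(.default_reference[e$covariate]) %||% NA_character_
      lev <- sort(unique(v))
      if (is.na(ref))
        ref <- names(sort(tapply(arms$n, v, sum), decreasing = TRUE))[1L]
      if (!ref %in% lev)
        stop_config("reference level '", ref, "' absent from covariate '",
                    e$covariate, "'")
      nonref <- setdiff(lev, ref)
      if (!length(nonref))
        stop_config("covariate '", e$covariate, "' has a single level")
      nm <- if (length(nonref) == 1L) e$covariate
            else paste(e$covariate, nonref, sep = ".")
      th <- e$theta
      if (!is.null(th)) {
        if (is.null(names(th)) && length(th) == length(nonref))
          names(th) <- nonref
        th <- unname(th[nonref])
        if (anyNA(th))
          stop_config("theta for '", e$covariate,
                      "' must name every non-reference level")
      }
      tm <- list(covariate = e$covariate, target = e$target, kind = kind,
                 reference = ref, levels = nonref, theta_names = nm,
                 theta = th)
    }
    theta_names <- c(theta_names, tm$theta_names)
    terms[[length(terms) + 1L]] <- tm
  }
  if (anyDuplicated(theta_names))
    stop_config("duplicate covariate theta names: ",
                theta_names[duplicated(theta_names)][1L])
  list(terms = terms, theta_names = theta_names)
}

## Per-arm multiplier on each target parameter given theta values (named by
## .resolve_effects()$theta_names). Returns a named list target -> vector.
.cov_multipliers <- function(resolved, arms, theta) {
  targets <- unique(vapply(resolved$terms, `[[`, "", "target"))
  out <- stats::setNames(
    rep(list(rep(1, nrow(arms))), length(targets)), targets)
  for (tm in resolved$terms) {
    if (tm$kind == "continuous") {
      th <- theta[[tm$theta_names]]
      m <- exp((arms[[tm$covariate]] - tm$cov_median) * th)
    } else {
      m <- rep(1, nrow(arms))
      for (i in seq_along(tm$levels)) {
        th <- theta[[tm$theta_names[i]]]
        if (th <= -1)
          stop_config("theta for '", tm$covariate,
                      "' must be > -1 to keep the parameter positive")
        m[arms[[tm$covariate]] == tm$levels[i]] <- 1 + th
      }
    }
    out[[tm$target]] <- out[[tm$target]] * m
  }
  out
}

#' Apply covariate effects to a typical parameter value
#'
#' @param p_typical typical (reference) value of the parameter.
#' @param profile a one-row data.frame or named list giving the covariate
#'   values of one arm.
#' @param effects list of [covariate_effect()] objects with `theta` (and,
#'   for continuous effects, `cov_median`) filled in.
#' @return the population parameter value for that profile.
#' @examples
#' e <- covariate_effect("therapy_type", theta = c(monotherapy = -0.215),
#'                       reference = "combination", kind = "categorical")
#' apply_covariate(2.96, list(therapy_type = "monotherapy"), list(e))  # 2.3236
#' @export
apply_covariate <- function(p_typical, profile, effects) {
  profile <- as.list(profile)
  out <- p_typical
  for (e in effects) {
    stopifnot(inherits(e, "covariate_effect"))
    if (is.null(e$theta)) stop_config("apply_covariate: theta not set for '",
                                      e$covariate, "'")
    val <- profile[[e$covariate]]
    if (is.null(val) || (length(val) == 1L && is.na(val)))
      stop_config("apply_covariate: profile lacks covariate '",
                  e$covariate, "'")
    kind <- e$kind %||% if (is.numeric(val)) "continuous" else "categorical"
    if (kind == "continuous") {
      if (is.null(e$cov_median))
        stop_config("apply_covariate: cov_median not set for '",
                    e$covariate, "'")
      out <- out * exp((val - e$cov_median) * e$theta)
    } else {
      th <- e$theta
      if (is.null(names(th)) && length(th) == 1L) {
        ## scalar theta: applies to any non-reference level
        if (is.null(e$reference))
          stop_config("apply_covariate: reference not set for '",
                      e$covariate, "'")
        f <- if (val == e$reference) 1 else 1 + th
      } else {
        f <- if (val %in% names(th)) 1 + th[[val]] else 1
      }
      out <- out * f
    }
  }
  out
}

#' Impute missing arm-level covariate values
#'
#' Blanks are replaced by the n-weighted median over non-missing arms.
#' Imputation always proceeds when any value is reported; separately, if
#' the patient-weighted missing fraction exceeds 30% the covariate is
#' flagged untestable, which excludes it from stepwise candidacy.
#'
#' @param corpus an `mbma_corpus`.
#' @param covariate name of a numeric arm-level column.
#' @return list with elements `corpus` (imputed), `report` (missing
#'   fraction, imputed value, `testable` flag).
#' @export
impute_missing <- function(corpus, covariate) {
  validate_corpus(corpus)
  arms <- corpus$arms
  if (!covariate %in% names(arms))
    stop_config("impute_missing: no covariate '", covariate, "'")
  v <- arms[[covariate]]
  if (!is.numeric(v))
    stop_config("impute_missing: '", covariate, "' is not numeric")
  miss <- is.na(v)
  frac <- sum(arms$n[miss]) / sum(arms$n)
  report <- list(covariate = covariate, missing_fraction = frac,
                 imputed_value = NA_real_, n_imputed = sum(miss),
                 testable = frac <= 0.30 && !all(miss))
  if (!all(miss) && any(miss)) {
    med <- weighted_median(v[!miss], arms$n[!miss])
    arms[[covariate]][miss] <- med
    report$imputed_value <- med
    corpus$arms <- arms
  }
  list(corpus = corpus, report = report)
}
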