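## Stepwise covariate selection by objective-function-value thresholds.
##
## Forward phase: each remaining candidate is added singly to the current
## model; the candidate with the largest OFV drop enters if the drop exceeds
## 2.71 (p < 0.1 on 1 df). Backward phase: each included covariate is
## removed singly from the full model; any whose removal fails to raise the
## OFV by more than 3.84 (p < 0.05) is deleted, worst first, iterating to
## stability.

#' Forward/backward stepwise covariate selection
#'
#' @param corpus an `mbma_corpus`.
#' @param base_model [mbma_model()] without the candidate covariates.
#' @param candidates character vector of arm-level covariate names, or a
#'   list of [covariate_effect()] declarations. Continuous candidates with
#'   missing values are median-imputed first; candidates missing in arms
#'   totalling more than 30% of patients are excluded as untestable.
#' @param seed integer seed passed to every fit.
#' @param forward_cut OFV drop required to enter (default 2.71).
#' @param backward_cut OFV rise required to stay (default 3.84).
#' @param compute_se compute standard errors on the final fit only.
#' @return an object of class `mbma_selection`: `trace` (one row per tested
#'   fit: phase, step, candidate, reference and candidate OFV, delta,
#'   action), `fit` (final `mbma_fit`), `model` (final model), `excluded`
#'   (untestable candidates), `corpus` (after imputation).
#' @export
select_covariates <- function(corpus, base_model, candidates, seed = 1L,
                              forward_cut = 2.71, backward_cut = 3.84,
                              compute_se = TRUE) {
  validate_corpus(corpus)
  stopifnot(inherits(base_model, "mbma_model"))
  if (is.character(candidates))
    candidates <- lapply(candidates, covariate_effect)
  ## impute continuous candidates; drop untestable ones
  excluded <- character(0)
  keep <- list()
  for (e in candidates) {
    v <- corpus$arms[[e$covariate]]
    if (is.null(v)) stop_config("candidate covariate '", e$covariate,
                                "' not in arms table")
    if (is.numeric(v) && anyNA(v)) {
      imp <- impute_missing(corpus, e$covariate)
      if (!imp$report$testable) {
        excluded <- c(excluded, e$covariate)
        next
      }
      corpus <- imp$corpus
    }
    keep[[length(keep) + 1L]] <- e
  }
  candidates <- keep
  cand_name <- vapply(candidates, `[[`, "", "covariate")

  fits <- new.env(parent = emptyenv())
  fit_set <- function(effs, warm = NULL) {
    sig <- paste(sort(vapply(effs, `[[`, "", "covariate")), collapse = "+")
    if (!is.null(fits[[paste0("k", sig)]])) return(fits[[paste0("k", sig)]])
    mod <- mbma_model(base_model$family, c(base_model$covariates, effs))
    f <- tryCatch(
      fit_mbma(corpus, mod, init = warm, seed = seed, compute_se = FALSE),
      error = function(e) NULL)
    fits[[paste0("k", sig)]] <- f
    f
  }
  warm_from <- function(fit) {
    if (is.null(fit)) return(NULL)
    info <- .family_info(fit$family)
    list(fixed = as.list(fit$theta[info$fixed]),
         theta = as.list(fit$theta[setdiff(names(fit$theta), info$fixed)]),
         omega = fit$omega, eps = fit$eps)
  }

  trace <- list()
  note <- function(phase, step, cand, ofv_ref, ofv_cand, action) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, step = step, candidate = cand,
      ofv_ref = ofv_ref, ofv_cand = ofv_cand,
      delta = ofv_ref - ofv_cand, action = action,
      stringsAsFactors = FALSE)
  }

  base_fit <- fit_set(list())
  if (is.null(base_fit) || !base_fit$converged)
    stop_config("select_covariates: base model failed to fit")
  included <- list()
  cur_fit <- base_fit
  step <- 0L

  ## forward inclusion
  remaining <- seq_along(candidates)
  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    deltas <- rep(NA_real_, length(remaining))
    cand_fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      ci <- remaining[i]
      f <- fit_set(c(included, candidates[ci]), warm = warm_from(cur_fit))
      cand_fits[[i]] <- f
      if (is.null(f) || !f$converged) {
        note("forward", step, cand_name[ci], cur_fit$ofv, NA_real_,
             "skipped_nonconverged")
      } else {
        deltas[i] <- cur_fit$ofv - f$ofv
        note("forward", step, cand_name[ci], cur_fit$ofv, f$ofv, "tested")
      }
    }
    if (all(is.na(deltas)) || max(deltas, na.rm = TRUE) <= forward_cut) break
    ## largest drop wins; near-ties (< 1e-6) go to declaration order
    best_d <- max(deltas, na.rm = TRUE)
    win <- which(!is.na(deltas) & deltas > best_d - 1e-6)[1L]
    note("forward", step, cand_name[remaining[win]], cur_fit$ofv,
         cand_fits[[win]]$ofv, "accepted")
    included <- c(included, candidates[remaining[win]])
    cur_fit <- cand_fits[[win]]
    remaining <- remaining[-win]
  }

  ## backward elimination
  repeat {
    if (!length(included)) break
    step <- step + 1L
    incl_names <- vapply(included, `[[`, "", "covariate")
    rises <- rep(NA_real_, length(included))
    red_fits <- vector("list", length(included))
    for (i in seq_along(included)) {
      f <- fit_set(included[-i], warm = warm_from(cur_fit))
      red_fits[[i]] <- f
      if (is.null(f) || !f$converged) {
        note("backward", step, incl_names[i], cur_fit$ofv, NA_real_,
             "skipped_nonconverged")
      } else {
        rises[i] <- f$ofv - cur_fit$ofv
        note("backward", step, incl_names[i], cur_fit$ofv, f$ofv, "tested")
      }
    }
    if (all(is.na(rises))) break
    worst <- which.min(rises)
    if (rises[worst] > backward_cut) break
    note("backward", step, incl_names[worst], cur_fit$ofv,
         red_fits[[worst]]$ofv, "removed")
    cur_fit <- red_fits[[worst]]
    included <- included[-worst]
  }

  final_model <- mbma_model(base_model$family,
                            c(base_model$covariates, included))
  final_fit <- if (compute_se)
    fit_mbma(corpus, final_model, init = warm_from(cur_fit), seed = seed,
             compute_se = TRUE)
  else cur_fit
  structure(list(
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(phase = character(0), step = integer(0),
                 candidate = character(0), ofv_ref = numeric(0),
                 ofv_cand = numeric(0), delta = numeric(0),
                 action = character(0)),
    fit = final_fit, model = final_model,
    selected = vapply(included, `[[`, "", "covariate"),
    excluded = excluded, corpus = corpus,
    forward_cut = forward_cut, backward_cut = backward_cut),
    class = "mbma_selection")
}

#' @export
print.mbma_selection <- function(x, ...) {
  cat("<mbma_selection> final covariates:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else
        "(none)", "\n")
  if (length(x$excluded))
    cat("  untestable (>30% missing):", paste(x$excluded, collapse = ", "),
        "\n")
  cat("  steps:\n")
  if (nrow(x$trace)) {
    tr <- x$trace
    for (i in seq_len(nrow(tr)))
      cat(sprintf("   %-8s %2d  %-14s dOFV %8.3f  %s\n", tr$phase[i],
                  tr$step[i], tr$candidate[i], tr$delta[i], tr$action[i]))
  } else cat("   (no candidates)\n")
  invisible(x)
}
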