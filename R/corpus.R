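## Arm-level survival corpus: container, validation, CSV I/O, summaries.
##
## A corpus holds aggregate progression-free-survival data, one observed
## survival fraction per (trial arm, time point), as digitized from published
## Kaplan-Meier curves. Arms carry the covariate profile of the modelled study
## population: therapy type, drug, biomarker, platinum sensitivity,
## combination partner, plus optional ECOG / age / blinding columns and any
## extra arm-level covariate columns supplied by the user.

.arm_required <- c("study_id", "arm_id", "n", "therapy_type", "drug",
                   "biomarker", "platinum", "partner")
.arm_optional <- c("ecog0_pct", "median_age", "blinded")
.obs_required <- c("study_id", "arm_id", "time", "obs_fraction")

.covariate_levels <- list(
  therapy_type = c("monotherapy", "combination"),
  drug         = c("olaparib", "niraparib", "rucaparib"),
  biomarker    = c("BRCAm", "BRCAwt", "HRD_positive"),
  platinum     = c("sensitive", "partially_resistant"),
  partner      = c("none", "chemotherapy", "bevacizumab", "cediranib"))

#' Binomial standard error of an observed survival fraction
#'
#' `sqrt(p * (1 - p) / n)`: the standard error that weights the combined
#' residual model. Zero at the boundary fractions 0 and 1.
#'
#' @param obs_fraction observed survival fraction in `[0, 1]` (vectorized).
#' @param n arm sample size, `>= 1`.
#' @return standard error, same length as the inputs after recycling.
#' @examples
#' residual_se(0.5, 100)  # 0.05
#' @export
residual_se <- function(obs_fraction, n) {
  if (any(n < 1)) stop("residual_se: n must be >= 1", call. = FALSE)
  if (any(obs_fraction < 0 | obs_fraction > 1))
    stop("residual_se: obs_fraction must lie in [0, 1]", call. = FALSE)
  sqrt(obs_fraction * (1 - obs_fraction) / n)
}

#' Construct a validated survival corpus
#'
#' @param arms data.frame with one row per trial arm: columns `study_id`,
#'   `arm_id`, `n`, `therapy_type`, `drug`, `biomarker`, `platinum`,
#'   `partner`, optionally `ecog0_pct`, `median_age`, `blinded`, and any
#'   further arm-level covariate columns.
#' @param obs data.frame with one row per observed Kaplan-Meier point:
#'   columns `study_id`, `arm_id`, `time` (months, > 0), `obs_fraction`
#'   (in `[0, 1]`), optionally `pred_fraction`. The `se` column is always
#'   recomputed via [residual_se()].
#' @param meta free-form provenance list.
#' @return an object of class `mbma_corpus` with elements `arms`, `obs`,
#'   `meta`.
#' @export
mbma_corpus <- function(arms, obs, meta = list()) {
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  arms$study_id <- as.character(arms$study_id)
  arms$arm_id <- as.character(arms$arm_id)
  obs$study_id <- as.character(obs$study_id)
  obs$arm_id <- as.character(obs$arm_id)
  if (is.null(obs$pred_fraction)) obs$pred_fraction <- NA_real_
  ## order arms by study then arm, observations by time within arm
  arms <- arms[order(arms$study_id, arms$arm_id), , drop = FALSE]
  obs <- obs[order(obs$study_id, obs$arm_id, obs$time), , drop = FALSE]
  rownames(arms) <- rownames(obs) <- NULL
  obs$se <- residual_se(obs$obs_fraction, arms$n[match(
    paste(obs$study_id, obs$arm_id), paste(arms$study_id, arms$arm_id))])
  x <- structure(list(arms = arms, obs = obs, meta = meta),
                 class = "mbma_corpus")
  validate_corpus(x)
  x
}

#' Validate a survival corpus
#'
#' Checks the structural invariants: required columns, covariate levels,
#' fractions in `[0, 1]`, strictly increasing times within arms, `n >= 1`,
#' unique arm identifiers, every arm observed at least once, `partner`
#' consistent with `therapy_type`, and the `se` column equal to
#' [residual_se()] of the observed fraction.
#'
#' @param corpus an `mbma_corpus`.
#' @return `corpus`, invisibly; errors name the offending study/arm/row.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "mbma_corpus"))
  arms <- corpus$arms; obs <- corpus$obs
  if (length(miss <- setdiff(.arm_required, names(arms))))
    stop_config("corpus: arms table lacks column(s) ",
                paste(miss, collapse = ", "))
  if (length(miss <- setdiff(.obs_required, names(obs))))
    stop_config("corpus: observations table lacks column(s) ",
                paste(miss, collapse = ", "))
  if (nrow(arms) < 1L) stop_config("corpus: needs at least one arm")
  key <- paste(arms$study_id, arms$arm_id)
  if (anyDuplicated(key))
    stop_config("corpus: duplicated arm id within study: ",
                key[duplicated(key)][1L])
  if (any(!is.finite(arms$n) | arms$n < 1 | arms$n != round(arms$n)))
    stop_config("corpus: n must be an integer >= 1 (arm ",
                key[which(!is.finite(arms$n) | arms$n < 1)[1L]], ")")
  for (cv in names(.covariate_levels)) {
    bad <- !arms[[cv]] %in% .covariate_levels[[cv]]
    if (any(bad))
      stop_config("corpus: invalid ", cv, " value '", arms[[cv]][bad][1L],
                  "' in arm ", key[bad][1L])
  }
  mono <- arms$therapy_type == "monotherapy"
  if (any(mono != (arms$partner == "none")))
    stop_config("corpus: partner must be 'none' iff monotherapy (arm ",
                key[which(mono != (arms$partner == "none"))[1L]], ")")
  okey <- paste(obs$study_id, obs$arm_id)
  if (length(orphan <- setdiff(unique(okey), key)))
    stop_config("corpus: observations reference unknown arm ", orphan[1L])
  if (length(empty <- setdiff(key, unique(okey))))
    stop_config("corpus: arm ", empty[1L], " has no observations")
  bad <- !is.finite(obs$obs_fraction) | obs$obs_fraction < 0 |
    obs$obs_fraction > 1
  if (any(bad))
    stop_config("corpus: obs_fraction outside [0, 1] in arm ",
                okey[bad][1L], " at time ", obs$time[bad][1L])
  if (any(obs$time <= 0))
    stop_config("corpus: observation times must be > 0 (arm ",
                okey[obs$time <= 0][1L], ")")
  for (k in unique(okey)) {
    tt <- obs$time[okey == k]
    if (any(diff(tt) <= 0))
      stop_config("corpus: times not strictly increasing in arm ", k)
  }
  n_of <- arms$n[match(okey, key)]
  if (max(abs(obs$se - residual_se(obs$obs_fraction, n_of))) > 1e-12)
    stop_config("corpus: se column inconsistent with residual_se")
  invisible(corpus)
}

#' @export
print.mbma_corpus <- function(x, ...) {
  cat("<mbma_corpus> ", length(unique(x$arms$study_id)), " studies, ",
      nrow(x$arms), " arms, ", nrow(x$obs), " observations, ",
      sum(x$arms$n), " patients\n", sep = "")
  invisible(x)
}

## columns written/read, in order: arm descriptors repeated per observation
.corpus_schema <- function(arms) {
  extra <- setdiff(names(arms), c(.arm_required, .arm_optional))
  c("study_id", "arm_id", "n", "therapy_type", "drug", "biomarker",
    "platinum", "partner",
    intersect(.arm_optional, names(arms)), extra,
    "time_months", "surv_fraction")
}

#' Read a survival corpus from CSV
#'
#' One row per (arm, time point); arm-level columns are repeated and must be
#' constant within an arm. Unknown columns are kept as extra arm-level
#' covariates. The `se` column is derived, never read.
#'
#' @param path CSV file with a header row.
#' @param schema optional named character vector mapping canonical column
#'   names (e.g. `time_months`) to the names used in the file.
#' @return an `mbma_corpus`.
#' @export
read_corpus <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_config("read_corpus: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop_config("read_corpus: schema maps '", canon, "' to missing ",
                    "column '", schema[[canon]], "'")
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  req <- c(.arm_required[.arm_required != "study_id"], "study_id",
           "time_months", "surv_fraction")
  if (length(miss <- setdiff(req, names(raw))))
    stop_config("read_corpus: missing required column(s): ",
                paste(miss, collapse = ", "))
  arm_cols <- setdiff(names(raw), c("time_months", "surv_fraction",
                                    "pred_fraction", "se"))
  key <- paste(raw$study_id, raw$arm_id)
  arms <- raw[!duplicated(key), arm_cols, drop = FALSE]
  ## arm-level columns must not vary within an arm
  for (cl in setdiff(arm_cols, c("study_id", "arm_id"))) {
    per <- tapply(raw[[cl]], key, function(v) length(unique(v)))
    if (any(per > 1L))
      stop_config("read_corpus: column '", cl, "' varies within arm ",
                  names(per)[per > 1L][1L])
  }
  if ("blinded" %in% names(arms)) arms$blinded <- as.logical(arms$blinded)
  obs <- data.frame(study_id = raw$study_id, arm_id = raw$arm_id,
                    time = raw$time_months, obs_fraction = raw$surv_fraction,
                    stringsAsFactors = FALSE)
  if ("pred_fraction" %in% names(raw)) obs$pred_fraction <- raw$pred_fraction
  mbma_corpus(arms, obs, meta = list(source = path))
}

#' Write a survival corpus to CSV
#'
#' Emits the same one-row-per-(arm, time) schema that [read_corpus()]
#' accepts; `read_corpus(write_corpus(x))` is lossless.
#'
#' @param corpus a valid `mbma_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  arms <- corpus$arms; obs <- corpus$obs
  i <- match(paste(obs$study_id, obs$arm_id), paste(arms$study_id, arms$arm_id))
  out <- arms[i, , drop = FALSE]
  out$time_months <- obs$time
  out$surv_fraction <- obs$obs_fraction
  out <- out[, .corpus_schema(arms), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Patient totals by covariate group
#'
#' Each patient is counted once per arm through the arm sample size `n`;
#' totals are reported for drug, biomarker, therapy type and platinum
#' status. For any of these partitions the group totals sum to the corpus
#' grand total.
#'
#' @param corpus a valid `mbma_corpus`.
#' @return data.frame with columns `variable`, `level`, `patients`.
#' @export
summarize_corpus <- function(corpus) {
  validate_corpus(corpus)
  arms <- corpus$arms
  one <- function(v) {
    tot <- tapply(arms$n, arms[[v]], sum)
    data.frame(variable = v, level = names(tot),
               patients = as.integer(unname(tot)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("drug", "biomarker", "therapy_type",
                                 "platinum", "partner"), one))
  rownames(out) <- NULL
  out
}

#' Combine two corpora with disjoint study ids
#'
#' @param x,y `mbma_corpus` objects; study ids must not overlap.
#' @return the combined `mbma_corpus`.
#' @export
corpus_bind <- function(x, y) {
  stopifnot(inherits(x, "mbma_corpus"), inherits(y, "mbma_corpus"))
  if (length(intersect(x$arms$study_id, y$arms$study_id)))
    stop_config("corpus_bind: overlapping study ids")
  common <- intersect(names(x$arms), names(y$arms))
  mbma_corpus(rbind(x$arms[common], y$arms[common]),
              rbind(x$obs[names(x$obs) != "se"], y$obs[names(y$obs) != "se"]),
              meta = c(x$meta, y$meta))
}
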