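#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted median
#'
#' Median of `x` with non-negative weights `w` (typically arm sample sizes).
#' When the cumulative weight hits exactly half the total at an observed value,
#' the midpoint of the two adjacent values is returned, so equal-weight pairs
#' average (e.g. 58 and 61 give 59.5).
#'
#' @param x numeric values.
#' @param w non-negative weights, recycled to `length(x)`.
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) stop("weighted_median: no finite values", call. = FALSE)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

## RNG hygiene: run `expr` under a seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(..., call. = FALSE)
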