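#' Round half away from zero
#'
#' Reported percentages are rounded to a fixed number of decimals with ties
#' going away from zero (so 3.45 -> 3.5 and -3.45 -> -3.5), unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  # nudge by a few ulps so values stored as 3.4499999... still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Median that tolerates missing values
#'
#' @param x numeric vector.
#' @return median of the non-missing values, or `NA_real_` if none remain.
#' @keywords internal
median_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_annodiff <- function(...) stop(..., call. = FALSE)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
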