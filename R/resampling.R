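#' Configuration for the subsampling representativeness procedure
#'
#' The procedure repeatedly (default 1000 times) subsamples a fixed number
#' of gene models (default 1000) without replacement from a full set and
#' recomputes a Spearman correlation coefficient on each subsample,
#' yielding an interval of coefficients against which a subset's
#' coefficient is classified. Sampling is without replacement within each
#' replicate; replicates are independent of each other (memberships may
#' overlap across replicates).
#'
#' @param n_replicates number of subsampling replicates (default 1000).
#' @param n_subsample models drawn per replicate (default 1000; must not
#'   exceed the number of usable rows of the full table).
#' @param seed master RNG seed; each replicate uses a sub-seed derived
#'   deterministically from it, so replicate k does not depend on
#'   `n_replicates`.
#' @param interval_mode `"range"` (min-max of the resampled coefficients,
#'   the default) or `"percentile"`.
#' @param percentile_bounds lower/upper percentiles for
#'   `interval_mode = "percentile"` (default `c(2.5, 97.5)`).
#' @return a `resampling_config` list.
#' @export
resampling_config <- function(n_replicates = 1000L, n_subsample = 1000L,
                              seed = 1L,
                              interval_mode = c("range", "percentile"),
                              percentile_bounds = c(2.5, 97.5)) {
  interval_mode <- match.arg(interval_mode)
  stopifnot(n_replicates >= 1L, n_subsample >= 2L,
            length(percentile_bounds) == 2L,
            percentile_bounds[1] < percentile_bounds[2])
  structure(list(n_replicates = as.integer(n_replicates),
                 n_subsample = as.integer(n_subsample),
                 seed = as.integer(seed),
                 interval_mode = interval_mode,
                 percentile_bounds = percentile_bounds),
            class = "resampling_config")
}

#' Resampled correlation coefficients of a full set
#'
#' Draws `n_replicates` subsamples of `n_subsample` rows (without
#' replacement within each replicate) from the usable rows of the full
#' property table and computes the Spearman coefficient of the requested
#' property pair on each, exactly as [correlate_all()] does on full sets.
#' Fully reproducible from `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param full_props property table of the full set (e.g. AUTO or OGS).
#' @param pair one of the four correlation pair names (see
#'   [correlate_all()]).
#' @param config a [resampling_config()].
#' @return numeric vector of length `n_replicates` of Spearman
#'   coefficients.
#' @export
subsample_r <- function(full_props, pair, config) {
  stopifnot(inherits(config, "resampling_config"))
  d <- correlation_pair_data(full_props, pair)
  n <- nrow(d)
  if (config$n_subsample > n) {
    stop_annodiff(sprintf(
      paste0("full table has only %d usable rows for pair '%s' but ",
             "n_subsample = %d; lower n_subsample"),
      n, pair, config$n_subsample))
  }
  rep_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L,
                                    config$n_replicates))
  vapply(seq_len(config$n_replicates), function(k) {
    idx <- with_seed(rep_seeds[k], sample.int(n, config$n_subsample))
    spearman_rho(d$x[idx], d$y[idx])$r
  }, numeric(1))
}

#' Interval spanned by resampled coefficients
#'
#' @param r_samples numeric vector of resampled coefficients.
#' @param config a [resampling_config()]; `interval_mode = "range"` gives
#'   the min-max interval, `"percentile"` the configured percentiles
#'   (linear interpolation).
#' @return named numeric vector `c(low, high)`.
#' @export
resample_interval <- function(r_samples, config) {
  stopifnot(inherits(config, "resampling_config"))
  r_samples <- r_samples[!is.na(r_samples)]
  if (length(r_samples) == 0L) stop_annodiff("no resampled coefficients")
  if (config$interval_mode == "range") {
    c(low = min(r_samples), high = max(r_samples))
  } else {
    q <- stats::quantile(r_samples, probs = config$percentile_bounds / 100,
                         names = FALSE, type = 7)
    c(low = q[1], high = q[2])
  }
}

#' Classify a subset coefficient against a resampling interval
#'
#' A subset whose coefficient falls below the interval minimum is
#' `"outside_low"`, above the maximum `"outside_high"`, otherwise
#' `"inside"`; equality with a bound counts as inside. An `NA` coefficient
#' yields `NA`.
#'
#' @param subset_r Spearman coefficient of the subset (scalar).
#' @param interval numeric `c(low, high)` from [resample_interval()].
#' @return `"inside"`, `"outside_low"`, `"outside_high"` or `NA`.
#' @export
classify_r <- function(subset_r, interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  if (is.na(subset_r)) return(NA_character_)
  if (subset_r < interval[1]) return("outside_low")
  if (subset_r > interval[2]) return("outside_high")
  "inside"
}

#' Representativeness assessment of subsets against a full set
#'
#' For each of the four correlation pairs, builds the resampling interval
#' from the full set and classifies each subset's coefficient against it.
#'
#' @param full_props property table of the full set.
#' @param full_label label of the full set (e.g. `"OGS"`).
#' @param subsets named list of subset property tables (e.g. `MAN-SUB`,
#'   `MAN-ADD`).
#' @param config a [resampling_config()].
#' @param pairs correlation pair names (default: all four).
#' @return a tibble with columns `full_set`, `pair`, `interval_low`,
#'   `interval_high`, `subset`, `subset_r`, `classification`.
#' @export
assess_representativeness <- function(full_props, full_label, subsets, config,
                                      pairs = names(CORRELATION_PAIRS)) {
  rows <- list()
  for (pair in pairs) {
    rs <- subsample_r(full_props, pair, config)
    iv <- resample_interval(rs, config)
    for (lab in names(subsets)) {
      d <- correlation_pair_data(subsets[[lab]], pair)
      r <- spearman_rho(d$x, d$y)$r
      rows[[length(rows) + 1L]] <- tibble::tibble(
        full_set = full_label, pair = pair,
        interval_low = iv[["low"]], interval_high = iv[["high"]],
        subset = lab, subset_r = r,
        classification = classify_r(r, iv))
    }
  }
  dplyr::bind_rows(rows)
}
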