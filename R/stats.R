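# Exact permutation distributions (tie-aware) -------------------------------
#
# For small samples the asymptotic KS and normal-approximation Wilcoxon
# p-values are poor, and stats::ks.test/stats::wilcox.test refuse exact
# computation in the presence of ties. Both exact p-values below are
# computed over the full permutation distribution of group labels by
# dynamic programming, which handles ties naturally:
#  - KS: lattice-path counting over tie groups. A label split is summarised
#    by the x-counts per tie group (multivariate hypergeometric); the
#    scaled discrepancy max |i*n2 - j*n1| is checked at tie-group
#    boundaries only.
#  - Wilcoxon: convolution counting subsets of size n1 by their (doubled,
#    hence integer) rank sum; two-sided p is the tail of |S - E[S]|.

ks_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- sort(unique(c(x, y)))
  ax <- tabulate(match(x, vals), nbins = length(vals))
  ay <- tabulate(match(y, vals), nbins = length(vals))
  m <- ax + ay
  # observed scaled discrepancy at group boundaries (integer arithmetic)
  M_obs <- max(abs(cumsum(ax) * n2 - cumsum(ay) * n1))
  D <- M_obs / (n1 * n2)
  if (M_obs == 0L) return(list(statistic = 0, p_value = 1))
  ways <- numeric(n1 + 1L)   # ways[i+1]: splits so far with i x-labels used
  ways[1L] <- 1
  c_total <- 0L
  for (g in seq_along(m)) {
    new <- numeric(n1 + 1L)
    kmax <- min(m[g], n1)
    for (k in 0L:kmax) {
      cg <- choose(m[g], k)
      if (k == 0L) new <- new + ways * cg
      else {
        idx <- seq_len(n1 + 1L - k)
        new[idx + k] <- new[idx + k] + ways[idx] * cg
      }
    }
    c_total <- c_total + m[g]
    i <- 0L:n1
    viol <- abs(i * n2 - (c_total - i) * n1) >= M_obs
    new[viol] <- 0
    ways <- new
  }
  inside <- ways[n1 + 1L]
  p <- 1 - inside / choose(n1 + n2, n1)
  list(statistic = D, p_value = min(max(p, 0), 1))
}

wilcox_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r2 <- as.integer(round(2 * rank(c(x, y))))  # doubled average ranks
  W <- sum(r2[seq_len(n1)]) / 2               # observed rank sum of x
  E2 <- n1 * (N + 1L)                         # doubled expected rank sum
  dev_obs <- abs(sum(r2[seq_len(n1)]) - E2)
  total <- sum(r2)
  # f[k+1, s+1] = number of size-k subsets with doubled rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (item in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      src <- seq_len(total + 1L - item)
      f[k + 1L, src + item] <- f[k + 1L, src + item] + f[k, src]
    }
  }
  counts <- f[n1 + 1L, ]
  s_vals <- 0:total
  p <- sum(counts[abs(s_vals - E2) >= dev_obs]) / choose(N, n1)
  list(statistic = W, p_value = min(max(p, 0), 1))
}

# ---------------------------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical distributions. The statistic is the supremum of
#' the absolute difference of the two ECDFs, evaluated with ties as-is.
#' For small samples (`n1 + n2 <= exact_limit`) the p-value is computed
#' exactly over the permutation distribution of group labels (tie-aware);
#' otherwise the asymptotic Kolmogorov distribution with effective sample
#' size `n1*n2/(n1+n2)` is used, via [stats::ks.test()], and is approximate
#' in the presence of ties.
#'
#' @param x,y numeric samples (non-empty; `NA`s removed).
#' @param method `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @param exact_limit maximum `n1 + n2` for which `"auto"` picks the exact
#'   computation (default 40).
#' @return a list with `statistic` (D), `p_value`, `n1`, `n2`, `method`.
#' @export
ks_two_sample <- function(x, y, method = c("auto", "exact", "asymptotic"),
                          exact_limit = 40L) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop_annodiff("empty sample")
  if (method == "auto") {
    method <- if (length(x) + length(y) <= exact_limit) "exact" else "asymptotic"
  }
  if (method == "exact") {
    res <- ks_exact_p(x, y)
  } else {
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    res <- list(statistic = unname(kt$statistic),
                p_value = min(max(unname(kt$p.value), 0), 1))
  }
  c(res, list(n1 = length(x), n2 = length(y), method = method))
}

#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Two-sided rank-sum test with average ranks for ties. The reported
#' statistic is the rank sum of `x` in the pooled sample. For small
#' samples the two-sided p-value is exact over the permutation
#' distribution (tie-aware, tail of `|S - E[S]|`); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used, via [stats::wilcox.test()]. Two samples with all values identical
#' give p = 1.
#'
#' @inheritParams ks_two_sample
#' @return a list with `statistic` (rank sum of `x`), `p_value`, `n1`,
#'   `n2`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "asymptotic"),
                              exact_limit = 40L) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop_annodiff("empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (method == "auto") {
    method <- if (N <= exact_limit) "exact" else "asymptotic"
  }
  W <- sum(rank(c(x, y))[seq_len(n1)])
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = W, p_value = 1, n1 = n1, n2 = n2,
                method = method))
  }
  if (method == "exact") {
    res <- wilcox_exact_p(x, y)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    p <- unname(wt$p.value)
    if (is.na(p) || is.nan(p)) p <- 1
    res <- list(statistic = W, p_value = min(max(p, 0), 1))
  }
  list(statistic = W, p_value = res$p_value, n1 = n1, n2 = n2,
       method = method)
}

#' Bonferroni correction
#'
#' Adjusts p-values for a family of `m` tests: `p_adj = min(1, m * p)`.
#'
#' @param p numeric vector of raw p-values.
#' @param m family size (defaults to `length(p)`); must be at least 1 and
#'   at least the number of p-values supplied.
#' @return vector of adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stop_annodiff("family size m must be >= 1")
  if (m < sum(!is.na(p))) {
    stop_annodiff("family size m smaller than number of p-values")
  }
  pmin(1, m * p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values. Pairs with an undefined
#' member are dropped (their count is reported); the coefficient is
#' undefined (`NA`) when fewer than two usable pairs remain or when either
#' ranked vector has zero variance.
#'
#' @param x,y paired numeric vectors.
#' @return a list with `r`, `n_used`, `n_dropped`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) {
    return(list(r = NA_real_, n_used = length(x), n_dropped = n_dropped))
  }
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  list(r = if (is.na(r)) NA_real_ else unname(r),
       n_used = length(x), n_dropped = n_dropped)
}

# property columns used for distribution comparisons
COMPARISON_PROPERTIES <- c("unspliced_length", "protein_length", "exon_count",
                           "median_exon_length", "median_intron_length")

#' All pairwise distribution tests between gene sets
#'
#' Runs, for every unordered pair of sets and each structural property, a
#' two-sample KS test and a two-sample Wilcoxon test. Undefined values
#' (e.g. intron medians of single-exon transcripts) are dropped per
#' property. Bonferroni correction is applied per test type over all tests
#' of that type in this invocation (KS tests corrected over KS tests,
#' Wilcoxon over Wilcoxon); tests that could not be run (an empty sample
#' after dropping `NA`s) carry `NA` statistics and do not count towards
#' the family size.
#'
#' @param sets named list of property tables (see [subset_properties()]).
#' @param properties property columns to compare (default: the five
#'   standard structural properties).
#' @param method passed to [ks_two_sample()] / [wilcoxon_rank_sum()].
#' @param alpha significance threshold applied to adjusted p-values for
#'   the `significant` flag (default 0.05).
#' @return a tibble with columns `test`, `set_a`, `set_b`, `property`,
#'   `statistic`, `p_raw`, `p_adj`, `n1`, `n2`, `significant`.
#' @export
compare_all <- function(sets, properties = COMPARISON_PROPERTIES,
                        method = "auto", alpha = 0.05) {
  if (length(sets) < 2L) stop_annodiff("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop_annodiff("sets must be named")
  }
  for (lab in names(sets)) {
    missing_cols <- setdiff(properties, names(sets[[lab]]))
    if (length(missing_cols) > 0L) {
      stop_annodiff("property column(s) absent from set '", lab, "': ",
                    paste(missing_cols, collapse = ", "))
    }
  }
  pairs <- utils::combn(names(sets), 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    for (p in properties) {
      x <- sets[[a]][[p]]; x <- x[!is.na(x)]
      y <- sets[[b]][[p]]; y <- y[!is.na(y)]
      if (length(x) == 0L || length(y) == 0L) {
        for (tn in c("KS", "W")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            test = tn, set_a = a, set_b = b, property = p,
            statistic = NA_real_, p_raw = NA_real_,
            n1 = length(x), n2 = length(y))
        }
        next
      }
      ks <- ks_two_sample(x, y, method = method)
      w <- wilcoxon_rank_sum(x, y, method = method)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "KS", set_a = a, set_b = b, property = p,
        statistic = ks$statistic, p_raw = ks$p_value,
        n1 = ks$n1, n2 = ks$n2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "W", set_a = a, set_b = b, property = p,
        statistic = w$statistic, p_raw = w$p_value,
        n1 = w$n1, n2 = w$n2)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- NA_real_
  for (tn in c("KS", "W")) {
    idx <- out$test == tn & !is.na(out$p_raw)
    m <- sum(idx)
    if (m > 0L) out$p_adj[idx] <- bonferroni_adjust(out$p_raw[idx], m)
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

# the four correlated property pairs: x column, y column, intron-based flag
CORRELATION_PAIRS <- list(
  exon_count_vs_exon_length = c("exon_count", "median_exon_length"),
  exon_count_vs_exon_gc = c("exon_count", "median_exon_gc"),
  intron_count_vs_intron_length = c("intron_count", "median_intron_length"),
  intron_count_vs_intron_gc = c("intron_count", "median_intron_gc"))

# extract the usable (x, y) data of one correlation pair from a property
# table; intron-based pairs are restricted to transcripts with introns
correlation_pair_data <- function(props, pair) {
  if (!pair %in% names(CORRELATION_PAIRS)) {
    stop_annodiff("unknown correlation pair: ", pair)
  }
  cols <- CORRELATION_PAIRS[[pair]]
  df <- props[cols]
  names(df) <- c("x", "y")
  if (startsWith(pair, "intron")) df <- df[props$intron_count >= 1L, ]
  df[!is.na(df$x) & !is.na(df$y), ]
}

#' Spearman correlations of the four property pairs, per set
#'
#' For every set, computes Spearman's rank correlation of (i) exon count
#' vs median exon length, (ii) exon count vs median exon GC, (iii) intron
#' count vs median intron length and (iv) intron count vs median intron
#' GC. Intron-based pairs use only transcripts with at least one intron.
#'
#' @param sets named list of property tables.
#' @return a tibble with columns `set_label`, `pair`, `r`, `n_used`,
#'   `n_dropped` (`r` is `NA` where fewer than two usable pairs remain).
#' @export
correlate_all <- function(sets) {
  rows <- list()
  for (lab in names(sets)) {
    for (pair in names(CORRELATION_PAIRS)) {
      d <- correlation_pair_data(sets[[lab]], pair)
      total <- if (startsWith(pair, "intron")) {
        sum(sets[[lab]]$intron_count >= 1L)
      } else nrow(sets[[lab]])
      res <- spearman_rho(d$x, d$y)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        set_label = lab, pair = pair, r = res$r,
        n_used = res$n_used, n_dropped = total - res$n_used)
    }
  }
  dplyr::bind_rows(rows)
}
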