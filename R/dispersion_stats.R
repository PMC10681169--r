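#' Dispersion statistics over included grid cells
#'
#' Computes the mean, variance, index of dispersion and coefficient of
#' variation of per-cell signal, over included cells only.
#'
#' The index of dispersion `D = variance / mean` is the primary statistic
#' for comparing deposition patterns: counts from complete spatial
#' randomness are Poisson, for which variance equals mean and `D = 1`;
#' `D >> 1` indicates clustering, `D < 1` low variance (spatial
#' regularity). The coefficient of variation `c_v = sd / mean` corroborates
#' `D` but, being scale-invariant, de-emphasizes the extreme deposition
#' areas that `D` is chosen to capture: multiplying all cell signals by
#' `k > 0` multiplies `D` by `k` and leaves `c_v` unchanged.
#'
#' The default variance convention is the sample variance (`n - 1`
#' denominator), appropriate for finite per-specimen samples of cells;
#' the population convention (`n` denominator) is available and the choice
#' is always recorded in the output. When the mean is 0 (no signal in any
#' included cell), `D` and `c_v` are flagged undefined rather than coerced
#' to 0 — silent zeros would fabricate perfect uniformity from empty
#' tissue.
#'
#' @param table a `quadrat_table` from [quantify_quadrats()], or a bare
#'   numeric vector of per-cell signals (all treated as included).
#' @param variance_convention `"sample"` (default) or `"population"`.
#' @return An object of class `dispersion_summary`: list with `n_cells`,
#'   `mean`, `variance`, `index_of_dispersion`, `coefficient_of_variation`
#'   (the last two `NA` with `defined = FALSE` when the mean is 0), and
#'   `variance_convention`.
#' @export
summarize_dispersion <- function(table,
                                 variance_convention = c("sample",
                                                         "population")) {
  variance_convention <- match.arg(variance_convention)
  x <- if (inherits(table, "quadrat_table"))
    table$signal[table$included] else as.numeric(table)
  n <- length(x)
  if (n == 0L)
    stop("no analyzable tissue: zero included cells")
  if (variance_convention == "sample" && n < 2L)
    stop("sample variance requires at least 2 included cells")
  m <- mean(x)
  v <- if (variance_convention == "sample") stats::var(x)
       else mean((x - m)^2)
  defined <- m > 0
  structure(list(n_cells = n, mean = m, variance = v,
                 index_of_dispersion = if (defined) v / m else NA_real_,
                 coefficient_of_variation = if (defined) sqrt(v) / m
                                            else NA_real_,
                 defined = defined,
                 variance_convention = variance_convention),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf("dispersion_summary: n = %d cells, mean = %.4g, %s variance = %.4g\n",
              x$n_cells, x$mean, x$variance_convention, x$variance))
  if (x$defined)
    cat(sprintf("  D = %.4g, c_v = %.4g\n",
                x$index_of_dispersion, x$coefficient_of_variation))
  else cat("  D and c_v undefined (mean signal is 0)\n")
  invisible(x)
}

#' Classify a dispersion pattern from its index of dispersion
#'
#' Thresholds `D` against the Poisson anchor `D = 1` with a configurable
#' band: `clustered` if `D > 1 + delta`, `underdispersed` (spatially
#' uniform/regular) if `D < 1 - delta`, otherwise `poisson_like`. An
#' undefined `D` propagates as `unclassifiable`.
#'
#' @param summary a `dispersion_summary` (or a bare numeric `D`).
#' @param delta half-width of the Poisson-compatible band (default 0.2).
#' @return One of `"clustered"`, `"poisson_like"`, `"underdispersed"`,
#'   `"unclassifiable"`.
#' @export
classify_pattern <- function(summary, delta = 0.2) {
  D <- if (inherits(summary, "dispersion_summary")) {
    if (!summary$defined) return("unclassifiable")
    summary$index_of_dispersion
  } else as.numeric(summary)
  if (is.na(D)) return("unclassifiable")
  if (D > 1 + delta) "clustered"
  else if (D < 1 - delta) "underdispersed"
  else "poisson_like"
}

#' Compare a statistic between two exposure groups
#'
#' Compares per-specimen values (index of dispersion, variance, or
#' peri-airway fraction) between two groups. The default is Welch's
#' two-sample t-test, two-sided: unequal variances between delivery-route
#' groups are expected (clustered deposition inflates the variance of the
#' clustered group), making the pooled-variance t inappropriate. A
#' permutation test on the difference of group means is available; it
#' enumerates all label assignments exactly when there are at most
#' `max_exact` of them, and otherwise draws `n_perm` seeded resamples.
#'
#' @param a,b numeric vectors of per-specimen values (each length >= 2),
#'   or lists of `dispersion_summary` objects (their `D` values are used).
#' @param test `"welch"` (default) or `"permutation"`.
#' @param n_perm number of Monte-Carlo resamples for the permutation test
#'   when exact enumeration is infeasible.
#' @param max_exact enumeration cutoff for the exact permutation test.
#' @param seed seed for Monte-Carlo resampling.
#' @return An object of class `group_comparison`: `statistic_name`,
#'   `statistic`, `p_value`, `n_a`, `n_b`, `test_spec` (full description
#'   of the test actually run).
#' @export
compare_groups <- function(a, b, test = c("welch", "permutation"),
                           n_perm = 10000L, max_exact = 20000L,
                           seed = 1L) {
  test <- match.arg(test)
  pull <- function(g) {
    if (is.list(g) && all(vapply(g, inherits, TRUE, "dispersion_summary")))
      vapply(g, function(s) s$index_of_dispersion, numeric(1))
    else as.numeric(g)
  }
  a <- pull(a); b <- pull(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 specimens")
  if (test == "welch") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      # degenerate constant, identical groups: no evidence of difference
      return(structure(list(statistic_name = "t", statistic = 0,
                            p_value = 1, n_a = length(a), n_b = length(b),
                            test_spec = "Welch two-sample t-test, two-sided (degenerate constant groups)"),
                       class = "group_comparison"))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    structure(list(statistic_name = "t",
                   statistic = unname(ht$statistic),
                   p_value = ht$p.value,
                   n_a = length(a), n_b = length(b),
                   test_spec = "Welch two-sample t-test on per-specimen values, two-sided, unequal variances"),
              class = "group_comparison")
  } else {
    obs <- mean(a) - mean(b)
    pool <- c(a, b); na <- length(a); n <- length(pool)
    ncomb <- choose(n, na)
    if (ncomb <= max_exact) {
      combs <- utils::combn(n, na)
      diffs <- apply(combs, 2, function(ix)
        mean(pool[ix]) - mean(pool[-ix]))
      p <- mean(abs(diffs) >= abs(obs) - 1e-12)
      spec <- sprintf("exact permutation test on difference of group means, two-sided, all %d label assignments", ncomb)
    } else {
      diffs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
        ix <- sample.int(n, na)
        mean(pool[ix]) - mean(pool[-ix])
      }, numeric(1)))
      p <- (1 + sum(abs(diffs) >= abs(obs) - 1e-12)) / (1 + n_perm)
      spec <- sprintf("Monte-Carlo permutation test on difference of group means, two-sided, %d resamples, seed %d", n_perm, seed)
    }
    structure(list(statistic_name = "mean difference", statistic = obs,
                   p_value = p, n_a = na, n_b = length(b),
                   test_spec = spec),
              class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (n = %d vs %d): %s = %.4g, p = %.5g\n",
              x$n_a, x$n_b, x$statistic_name, x$statistic, x$p_value))
  cat("  test:", x$test_spec, "\n")
  invisible(x)
}
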