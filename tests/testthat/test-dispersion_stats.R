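test_that("dispersion summaries match hand-computed values", {
  s <- summarize_dispersion(c(2, 2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$variance, 0)
  expect_equal(s$index_of_dispersion, 0)
  expect_equal(s$coefficient_of_variation, 0)

  s <- summarize_dispersion(c(0, 0, 0, 8))  # sample convention
  expect_equal(s$mean, 2)
  expect_equal(s$variance, 16)
  expect_equal(s$index_of_dispersion, 8)
  expect_equal(s$coefficient_of_variation, 2)

  s <- summarize_dispersion(c(0, 0, 0, 8), "population")
  expect_equal(s$variance, 12)
  expect_equal(s$index_of_dispersion, 6)
})

test_that("degenerate inputs are flagged, never silently coerced", {
  expect_error(summarize_dispersion(numeric(0)), "no analyzable tissue")
  expect_error(summarize_dispersion(5), "at least 2")
  expect_silent(summarize_dispersion(5, "population"))
  s <- summarize_dispersion(c(0, 0, 0))
  expect_false(s$defined)
  expect_true(is.na(s$index_of_dispersion))
  expect_true(is.na(s$coefficient_of_variation))
  expect_identical(classify_pattern(s), "unclassifiable")
})

test_that("summaries agree with a naive two-pass oracle to 1e-12", {
  set.seed(31)
  for (i in 1:20) {
    x <- rgamma(sample(5:400, 1), shape = 2, rate = 0.5)
    s <- summarize_dispersion(x)
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    expect_equal(s$mean, m, tolerance = 1e-12)
    expect_equal(s$variance, v, tolerance = 1e-12)
    expect_equal(s$index_of_dispersion, v / m, tolerance = 1e-12)
    expect_equal(s$coefficient_of_variation, sqrt(v) / m, tolerance = 1e-12)
  }
})

test_that("Poisson counts recover D near 1 and the estimator is calibrated", {
  set.seed(32)
  D1 <- summarize_dispersion(rpois(600, 3))$index_of_dispersion
  expect_gt(D1, 0.9); expect_lt(D1, 1.1)

  # 800 cells per simulation keeps sd(D) near 0.05, so the [0.9, 1.1]
  # band holds ~95% of draws in expectation
  Ds <- vapply(1:200, function(i)
    summarize_dispersion(rpois(800, 3))$index_of_dispersion, numeric(1))
  expect_gt(mean(Ds), 0.97); expect_lt(mean(Ds), 1.03)
  expect_gt(mean(Ds > 0.9 & Ds < 1.1), 0.90)
})

test_that("pattern classification thresholds around the Poisson anchor", {
  expect_identical(classify_pattern(41.90), "clustered")
  expect_identical(classify_pattern(0.627), "underdispersed")
  expect_identical(classify_pattern(1.0), "poisson_like")
  expect_identical(classify_pattern(1.15), "poisson_like")
  expect_identical(classify_pattern(1.15, delta = 0.1), "clustered")
})

test_that("D scales with signal magnitude while c_v is scale-invariant", {
  set.seed(33)
  x <- rpois(200, 4)
  s1 <- summarize_dispersion(x)
  for (k in c(0.5, 3, 10)) {
    sk <- summarize_dispersion(k * x)
    expect_equal(sk$index_of_dispersion, k * s1$index_of_dispersion)
    expect_equal(sk$coefficient_of_variation, s1$coefficient_of_variation)
  }
})

test_that("Welch comparison matches a closed-form oracle and handles identity", {
  a <- c(1, 1, 1); b <- c(100, 101, 102)
  cmp <- compare_groups(a, b)
  expect_lt(cmp$p_value, 0.01)
  # closed-form Welch t
  t_manual <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(cmp$statistic, t_manual)
  # two-sided symmetry
  rev <- compare_groups(b, a)
  expect_equal(rev$p_value, cmp$p_value)
  expect_equal(rev$statistic, -cmp$statistic)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  const <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(const$p_value, 1)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("exact permutation p-values have the combinatorial granularity", {
  a <- c(1.3, 2.1, 0.7); b <- c(5.2, 6.8, 4.9)
  cmp <- compare_groups(a, b, test = "permutation")
  expect_match(cmp$test_spec, "all 20 label assignments")
  expect_equal((cmp$p_value * choose(6, 3)) %% 1, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 / 20)  # only the two extreme assignments

  ident <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "permutation")
  expect_gt(ident$p_value, 0.99)
})
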