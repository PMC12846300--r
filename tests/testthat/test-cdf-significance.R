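test_that("the empirical case CDF follows the sorted label fractions", {
  expect_equal(empirical_case_cdf(c(1, 2, 3, 4), c(0, 0, 1, 1)),
               c(0, 0, 0.5, 1))
  # all-cancer labels give the straight line j/n
  expect_equal(empirical_case_cdf(c(5, 2, 9), c(1, 1, 1)), (1:3) / 3)
  # depends only on the ordering of the intensities
  x <- rnorm(10)
  y <- rep(c(0, 1), 5)
  expect_identical(empirical_case_cdf(x, y), empirical_case_cdf(2^x, y))
  expect_error(empirical_case_cdf(c(1, 2), c(0, 0)), "no cancer")
})

test_that("surrogate and real CDFs are valid distribution profiles", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    y <- integer(n); y[sample(n, sample(1:(n - 1), 1))] <- 1L
    cdf <- empirical_case_cdf(rnorm(n), y)
    expect_true(all(diff(cdf) >= 0))
    expect_gte(cdf[1], 0)
    expect_equal(cdf[n], 1)
  }
})

test_that("exact-mode S agrees with the brute-force enumeration oracle", {
  # n = 4 fixture, frozen from the enumeration over all 6 assignments
  expect_equal(s_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1),
                           exact_mode = TRUE),
               1.5811388, tolerance = 1e-6)
  expect_equal(s_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1),
                           exact_mode = TRUE),
               oracle_s_exact(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  # n = 6 fixtures, unbalanced orderings included
  x6 <- c(5, 1, 3, 2, 6, 4); y6 <- c(1, 0, 1, 0, 1, 0)
  expect_equal(s_statistic(x6, y6, exact_mode = TRUE),
               oracle_s_exact(x6, y6))
  expect_equal(s_statistic(1:6, c(0, 0, 0, 1, 1, 1), exact_mode = TRUE),
               oracle_s_exact(1:6, c(0, 0, 0, 1, 1, 1)))
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- integer(6); y[sample(6, 3)] <- 1L
    expect_equal(s_statistic(x, y, exact_mode = TRUE), oracle_s_exact(x, y))
  }
})

test_that("S is invariant under monotone transforms for a fixed seed", {
  set.seed(12)
  x <- rnorm(12, 20, 2)   # tie-free with probability 1
  y <- rep(c(0, 1), each = 6)
  expect_identical(s_statistic(x, y, B = 500, seed = 3),
                   s_statistic(2^x, y, B = 500, seed = 3))
})

test_that("sampled permutations converge to the exact null at n = 12", {
  set.seed(40)
  for (i in 1:3) {
    x <- rnorm(12, 20, 2)
    y <- sample(rep(c(0L, 1L), each = 6))
    s_exact <- s_statistic(x, y, exact_mode = TRUE)
    s_samp <- s_statistic(x, y, B = 20000, seed = i)
    expect_lt(abs(s_samp - s_exact), 0.15)
  }
})

test_that("label-randomized data rarely reach S >= 3", {
  set.seed(42)
  m <- matrix(rnorm(250 * 12), 250, 12,
              dimnames = list(NULL, sprintf("s%02d", 1:12)))
  tab <- make_table(m)
  res <- cdf_significance(tab, balanced_labels(), B = 1000, seed = 7)
  expect_lt(mean(res$S >= 3), 0.05)
})

test_that("significance bands follow the fixed S cutpoints", {
  expect_equal(as.character(classify_band(c(3.2944, 2.8358, 0.99, 1.0,
                                            2.0, 3.0, 0))),
               c("high", "moderate", "nonsignificant", "low",
                 "moderate", "high", "nonsignificant"))
  expect_error(classify_band(-0.1), "non-negative")
})

test_that("band census partitions the set and reports both threshold conventions", {
  bands <- c(rep("high", 2), rep("moderate", 79), rep("low", 81),
             "nonsignificant")
  cen <- band_census(bands)
  expect_equal(cen$n_total, 163)
  expect_equal(unname(cen$percentages),
               c(1.2, 48.5, 49.7, 0.6))
  expect_equal(cen$n_ge_2, 81)
  expect_equal(cen$n_ge_1, 162)

  one <- band_census(2.5)
  expect_equal(unname(one$percentages["moderate"]), 100)
  expect_equal(sum(one$counts), 1)
  expect_equal(unname(one$counts[c("high", "low", "nonsignificant")]),
               c(0L, 0L, 0L))
  expect_equal(unname(one$percentages["high"]), 0)

  # numeric input reports strict and inclusive counts separately
  num <- band_census(c(2, 2.5, 1.2, 0.4))
  expect_equal(num$n_gt_2, 1)
  expect_equal(num$n_ge_2, 2)
  expect_error(band_census(character(0)), "empty")
})

test_that("table-wide analysis is deterministic and matches the scalar path", {
  set.seed(5)
  m <- matrix(rnorm(8 * 12, 20, 2), 8, 12,
              dimnames = list(NULL, sprintf("s%02d", 1:12)))
  tab <- make_table(m)
  lab <- balanced_labels()
  r1 <- cdf_significance(tab, lab, B = 800, seed = 9)
  r2 <- cdf_significance(tab, lab, B = 800, seed = 9)
  expect_identical(r1, r2)
  # scalar s_statistic with the same seed uses the same surrogate stream
  expect_equal(r1$S[1],
               s_statistic(m[1, ], unclass(lab), B = 800, seed = 9))
  expect_error(cdf_significance(make_table(matrix(c(NA, 1, 2, 3), 2, 2)),
                                balanced_labels(1, 1, c("s01", "s02"))),
               "completed")
})

test_that("truly differential peptides rank above null peptides by S", {
  meds <- vapply(1:5, function(s) {
    g <- generate_cohort(cohort_spec(seed = s))
    imp <- impute_minprob(g$table, seed = s + 100)
    flt <- filter_min_samples(imp$table, g$labels, imp$imputed_mask, 4)
    col <- collapse_duplicates(flt$table)
    res <- cdf_significance(col, g$labels, B = 300, seed = s + 200)
    truth <- g$truth$differential[match(res$peptide, g$truth$peptide)]
    median(res$S[truth]) - median(res$S[!truth])
  }, 0)
  expect_true(all(meds > 0))
})
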