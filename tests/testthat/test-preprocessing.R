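test_that("log2 transform inverts exp2 and rejects non-positive values", {
  m <- matrix(c(1, 8, 0.5, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  tab <- make_table(m, scale = "linear")
  lg <- to_log2(tab)
  expect_equal(unname(lg$intensity[1, 1]), 0)
  expect_equal(unname(lg$intensity[2, 1]), 3)
  expect_identical(is.na(lg$intensity), is.na(m))
  expect_equal(lg$scale, "log2")
  expect_error(to_log2(lg), "already")

  set.seed(1)
  r <- matrix(2^rnorm(40, 20, 2), 10, 4)
  rt <- to_log2(make_table(r, scale = "linear"))
  expect_equal(2^rt$intensity, r, tolerance = 1e-12, ignore_attr = TRUE)

  bad <- make_table(matrix(c(1, -2, 3, 4), 2, 2,
                           dimnames = list(NULL, c("a", "b"))),
                    scale = "linear")
  expect_error(to_log2(bad), "row 2, sample 'a'")
})

test_that("sd_of_observed matches the two-pass textbook formula", {
  expect_equal(sd_of_observed(c(5, 5, 5)), 0)
  expect_equal(sd_of_observed(c(0, 2)), sqrt(2))
  expect_error(sd_of_observed(c(1, NA)), "at least 2")
  set.seed(7)
  v <- rnorm(101)
  two_pass <- sqrt(sum((v - sum(v) / length(v))^2) / (length(v) - 1))
  expect_equal(sd_of_observed(v), two_pass, tolerance = 1e-12)
})

test_that("imputation fills missing cells from the shifted column model", {
  # identity case: nothing missing
  full <- make_table(matrix(rnorm(24, 20), 4, 6))
  res <- impute_minprob(full, seed = 1)
  expect_identical(res$table$intensity, full$intensity)
  expect_false(any(res$imputed_mask))

  # width = 0: every imputed value is exactly mu - 1.8 sigma of its column
  m <- matrix(rnorm(60, 20, 2), 10, 6,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  m[cbind(c(1, 4, 7), c(2, 2, 5))] <- NA
  res0 <- impute_minprob(make_table(m), downshift = 1.8, width = 0, seed = 3)
  for (j in c(2, 5)) {
    obs <- m[!is.na(m[, j]), j]
    expect_equal(unname(res0$table$intensity[is.na(m[, j]), j]),
                 rep(mean(obs) - 1.8 * sd(obs), sum(is.na(m[, j]))))
  }

  # moment recovery at 10^4 missing cells in one column
  n_miss <- 10000
  col <- c(rnorm(50, 20, 2), rep(NA, n_miss))
  big <- cbind(a = col, b = rnorm(length(col), 20, 2))
  res1 <- impute_minprob(make_table(big), downshift = 1.8, width = 0.3,
                         seed = 5)
  mu <- mean(col, na.rm = TRUE); sg <- sd(col[!is.na(col)])
  imputed <- res1$table$intensity[is.na(col), "a"]
  se_mean <- 0.3 * sg / sqrt(n_miss)
  expect_lt(abs(mean(imputed) - (mu - 1.8 * sg)), 3 * se_mean)
  se_sd <- 0.3 * sg / sqrt(2 * (n_miss - 1))
  expect_lt(abs(sd(imputed) - 0.3 * sg), 3 * se_sd)
})

test_that("imputation never alters observed cells and is seed-stable", {
  for (s in 1:3) {
    g <- generate_cohort(cohort_spec(n_peptides = 40, seed = s))
    r1 <- impute_minprob(g$table, seed = s)
    r2 <- impute_minprob(g$table, seed = s)
    expect_identical(r1, r2)
    obs <- !is.na(g$table$intensity)
    expect_identical(r1$table$intensity[obs], g$table$intensity[obs])
    expect_identical(r1$imputed_mask, is.na(g$table$intensity))
  }
  thin <- make_table(matrix(c(1, NA, NA, 2, 3, 4), 3, 2,
                            dimnames = list(NULL, c("bad", "ok"))))
  expect_error(impute_minprob(thin), "bad")
})

test_that("coverage filter applies the per-group observed-count rule", {
  prof <- data.frame(n_obs_control = c(2, 6, 4), n_obs_cancer = c(6, 2, 4))
  fx <- generate_filter_fixture(prof)
  # the filter consults only the observed/imputed mask, so it can run on
  # the un-imputed table with the missing mask standing in
  mask <- is.na(fx$table$intensity)
  out <- filter_min_samples(fx$table, fx$labels, mask, 3)
  expect_equal(out$report$retained_peptides, 1)
  expect_equal(out$report$removed_peptides, 2)
  expect_equal(out$report$removed_values_total, 2 * 12)
  expect_equal(out$table$meta$peptide, fx$table$meta$peptide[3])

  none <- filter_min_samples(fx$table, fx$labels, mask, 0)
  expect_equal(none$report$removed_peptides, 0)
  expect_equal(nrow(none$table$intensity), 3)

  expect_error(filter_min_samples(fx$table, fx$labels, mask, 7),
               "exceeds a group size")
})

test_that("filter-report partition identities hold on random cohorts", {
  for (s in 1:3) {
    g <- generate_cohort(cohort_spec(n_peptides = 60, seed = s))
    imp <- impute_minprob(g$table, seed = s)
    n_obs_total <- sum(!imp$imputed_mask)
    n_imp_total <- sum(imp$imputed_mask)
    for (ms in 2:4) {
      rep <- filter_min_samples(imp$table, g$labels, imp$imputed_mask,
                                ms)$report
      expect_equal(rep$removed_peptides + rep$retained_peptides,
                   nrow(g$table$intensity))
      expect_equal(rep$removed_values_total,
                   rep$removed_peptides * rep$n_samples)
      expect_equal(rep$removed_values_observed + rep$retained_values_observed,
                   n_obs_total)
      expect_equal(rep$removed_values_imputed + rep$retained_values_imputed,
                   n_imp_total)
    }
  }
  expect_error(filter_report(4, 12, removed_peptides = 2,
                             retained_peptides = 1,
                             removed_values_observed = 10,
                             removed_values_imputed = 10,
                             retained_values_observed = 10,
                             retained_values_imputed = 2),
               "inconsistent")
})

test_that("duplicate collapsing averages on the log2 scale", {
  m <- matrix(c(10, 14, 5,
                20, 20, 6), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  tab <- peptide_table(m, peptide = c("K.AAA.R", "K.AAA.R", "K.BBB.R"),
                       protein_id = c("P1", "Pother", "P2"),
                       flank_context = c("f1", "f2", "f3"))
  col <- collapse_duplicates(tab)
  expect_equal(nrow(col$intensity), 2)
  expect_equal(unname(col$intensity[1, ]), c(12, 20))
  # metadata from the first occurrence, first-occurrence order kept
  expect_equal(col$meta$protein_id, c("P1", "P2"))
  expect_equal(col$meta$flank_context, c("f1", "f3"))

  # identity on duplicate-free tables, idempotence in general
  uniq <- make_table(matrix(rnorm(20, 20), 5, 4))
  expect_identical(collapse_duplicates(uniq), uniq)
  expect_identical(collapse_duplicates(collapse_duplicates(tab)), col)

  # two identical duplicate rows collapse to the same values
  same <- peptide_table(matrix(c(7, 7, 8, 8), 2, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        peptide = c("K.CCC.R", "K.CCC.R"),
                        protein_id = c("P", "P"))
  expect_equal(unname(collapse_duplicates(same)$intensity[1, ]), c(7, 8))
})

test_that("on complete data the imputation stage is a no-op in the pipeline order", {
  g <- generate_cohort(cohort_spec(n_peptides = 30, n_duplicate_rows = 5,
                                   dropout_steepness = Inf,
                                   dropout_midpoint_log2 = -100, seed = 5))
  imp <- impute_minprob(g$table, seed = 1)
  with_imp <- collapse_duplicates(
    filter_min_samples(imp$table, g$labels, imp$imputed_mask, 4)$table)
  without <- collapse_duplicates(
    filter_min_samples(g$table, g$labels, is.na(g$table$intensity),
                       4)$table)
  expect_identical(with_imp, without)
})

test_that("peptide tables and sample sheets round-trip through TSV", {
  g <- generate_cohort(cohort_spec(n_peptides = 20, seed = 8))
  f <- tempfile(fileext = ".tsv")
  write_peptide_table(g$table, f)
  back <- read_peptide_table(f, scale = "log2")
  expect_equal(back$intensity, g$table$intensity, tolerance = 1e-9)
  expect_equal(back$meta$peptide, g$table$meta$peptide)
  fs <- tempfile(fileext = ".tsv")
  write_sample_sheet(g$labels, fs)
  expect_identical(read_sample_sheet(fs), g$labels)
})

test_that("dataset accounting derives totals and missing percentage", {
  acc <- dataset_accounting(10, 4, 8)
  expect_equal(acc$total_observations, 40)
  expect_equal(acc$n_observed, 32)
  expect_equal(acc$pct_missing, 20)
  expect_error(dataset_accounting(10, 4, 41), "invalid")
})
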