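#' Log2-transform a linear-scale peptide table
#'
#' @param table a [peptide_table] with `scale == "linear"`; all observed
#'   values must be strictly positive.
#' @return The table with observed values replaced by their base-2
#'   logarithm and `scale` set to `"log2"`; the missing mask is unchanged.
#' @export
to_log2 <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  if (table$scale != "linear")
    stop("table is already on the log2 scale")
  bad <- which(!is.na(table$intensity) & table$intensity <= 0,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-positive intensity at peptide row %d, sample '%s'",
      bad[1, 1], colnames(table$intensity)[bad[1, 2]]))
  table$intensity <- log2(table$intensity)
  table$scale <- "log2"
  table
}

#' Sample standard deviation of observed values
#'
#' SD of the non-missing values with the n-1 (sample) denominator, as used
#' for the per-sample moments of left-censored imputation.
#'
#' @param values numeric vector, possibly containing `NA`.
#' @return The sample standard deviation.
#' @export
sd_of_observed <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2)
    stop("at least 2 observed values are required to estimate sigma")
  stats::sd(obs)
}

#' Left-censored (MinProb) imputation of missing intensities
#'
#' Replaces each missing log2 intensity with a draw from a narrow normal
#' distribution shifted below the sample's observed mean:
#' `mu - downshift * sigma + width * sigma * eps`, `eps ~ N(0, 1)`, where
#' `mu` and `sigma` are the mean and SD of the observed values of that
#' sample (column). Each sample is imputed independently, preserving its
#' intensity distribution; the mechanism encodes the assumption that
#' missing values are low-abundance signals below the detection limit.
#'
#' Random draws consume a single RNG stream in column-major order (sample
#' by sample, missing cells in row order), so results are reproducible and
#' order-stable for a fixed seed.
#'
#' @param table a [peptide_table] on the log2 scale. Every sample column
#'   must have at least 2 observed values.
#' @param downshift how many observed-SD units below the observed mean the
#'   imputed distribution is centred (default 1.8).
#' @param width spread of the imputed distribution in observed-SD units
#'   (default 0.3).
#' @param seed RNG seed.
#' @return A list of class `minprob_imputation`:
#'   `table` (completed [peptide_table], no missing values),
#'   `imputed_mask` (logical matrix, `TRUE` where a value was imputed;
#'   equals the input missing mask),
#'   `column_stats` (data.frame of per-sample `mu`, `sigma`, `n_observed`,
#'   `n_imputed`).
#' @export
impute_minprob <- function(table, downshift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(inherits(table, "peptide_table"))
  if (table$scale != "log2")
    stop("imputation requires log2-scale intensities; call to_log2() first")
  if (width < 0 || downshift < 0)
    stop("'downshift' and 'width' must be non-negative")
  x <- table$intensity
  mask <- is.na(x)
  n_obs <- colSums(!mask)
  if (any(n_obs < 2))
    stop("cannot impute sample(s) with fewer than 2 observed values: ",
         paste(colnames(x)[n_obs < 2], collapse = ", "))
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- apply(x, 2, sd_of_observed)
  set.seed(seed)
  for (j in seq_len(ncol(x))) {
    miss <- which(mask[, j])
    if (length(miss))
      x[miss, j] <- mu[j] - downshift * sigma[j] +
        width * sigma[j] * stats::rnorm(length(miss))
  }
  out <- table
  out$intensity <- x
  structure(list(
    table = out,
    imputed_mask = mask,
    column_stats = data.frame(sample_id = colnames(x), mu = mu,
                              sigma = sigma, n_observed = n_obs,
                              n_imputed = colSums(mask),
                              row.names = NULL)
  ), class = "minprob_imputation")
}

#' Coverage-filter removal accounting
#'
#' Assembles the full bookkeeping of a minimum-coverage filtering step from
#' its raw counts, deriving every total and percentage and validating the
#' partition identities (e.g. removed values = removed peptides x samples,
#' since the filter acts on a completed matrix). This is both the report
#' attached to [filter_min_samples()] results and a standalone calculator
#' for checking a published removal accounting.
#'
#' Two observed-value ratios are reported for the retained set, because
#' they answer different questions: `pct_retained_observed_of_retained`
#' (what fraction of retained entries is directly measured) and
#' `pct_retained_observed_of_observed` (what fraction of all measured
#' entries survives the filter).
#'
#' @param min_samples the per-group coverage threshold applied.
#' @param n_samples total number of samples (columns).
#' @param removed_peptides,retained_peptides peptide counts.
#' @param removed_values_observed,removed_values_imputed partition of the
#'   removed entries.
#' @param retained_values_observed,retained_values_imputed partition of the
#'   retained entries.
#' @return A list of class `filter_report` with the input counts plus
#'   `n_peptides_in`, `removed_values_total`, `retained_values_total`,
#'   `total_observed`, `total_imputed`, `total_values`, and percentage
#'   fields (1-decimal): `pct_peptides_removed`, `pct_missing`,
#'   `pct_removed_observed_of_observed`, `pct_removed_imputed_of_imputed`,
#'   `pct_retained_observed_of_retained`,
#'   `pct_retained_observed_of_observed`.
#' @export
filter_report <- function(min_samples, n_samples,
                          removed_peptides, retained_peptides,
                          removed_values_observed, removed_values_imputed,
                          retained_values_observed,
                          retained_values_imputed) {
  removed_values_total <- removed_values_observed + removed_values_imputed
  retained_values_total <- retained_values_observed + retained_values_imputed
  if (removed_values_total != removed_peptides * n_samples)
    stop("inconsistent counts: removed values must equal removed peptides x samples")
  if (retained_values_total != retained_peptides * n_samples)
    stop("inconsistent counts: retained values must equal retained peptides x samples")
  n_peptides_in <- removed_peptides + retained_peptides
  total_observed <- removed_values_observed + retained_values_observed
  total_imputed <- removed_values_imputed + retained_values_imputed
  total_values <- total_observed + total_imputed
  pct <- function(a, b) if (b > 0) round(100 * a / b, 1) else 0
  structure(list(
    min_samples = min_samples, n_samples = n_samples,
    n_peptides_in = n_peptides_in,
    removed_peptides = removed_peptides,
    retained_peptides = retained_peptides,
    removed_values_total = removed_values_total,
    removed_values_observed = removed_values_observed,
    removed_values_imputed = removed_values_imputed,
    retained_values_total = retained_values_total,
    retained_values_observed = retained_values_observed,
    retained_values_imputed = retained_values_imputed,
    total_observed = total_observed,
    total_imputed = total_imputed,
    total_values = total_values,
    pct_peptides_removed = pct(removed_peptides, n_peptides_in),
    pct_missing = pct(total_imputed, total_values),
    pct_removed_observed_of_observed = pct(removed_values_observed,
                                           total_observed),
    pct_removed_imputed_of_imputed = pct(removed_values_imputed,
                                         total_imputed),
    pct_retained_observed_of_retained = pct(retained_values_observed,
                                            retained_values_total),
    pct_retained_observed_of_observed = pct(retained_values_observed,
                                            total_observed)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("minSamples = %d filter on %d peptides x %d samples\n",
              x$min_samples, x$n_peptides_in, x$n_samples))
  cat(sprintf("  removed: %d peptides (%.1f%%), %d values (%d observed [%.1f%% of observed], %d imputed [%.1f%% of imputed])\n",
              x$removed_peptides, x$pct_peptides_removed,
              x$removed_values_total, x$removed_values_observed,
              x$pct_removed_observed_of_observed, x$removed_values_imputed,
              x$pct_removed_imputed_of_imputed))
  cat(sprintf("  retained: %d peptides, %d values (%d observed [%.1f%% of retained], %d imputed)\n",
              x$retained_peptides, x$retained_values_total,
              x$retained_values_observed,
              x$pct_retained_observed_of_retained,
              x$retained_values_imputed))
  invisible(x)
}

#' Dataset-dimension accounting
#'
#' Total observation count and missing percentage for a peptide matrix of
#' given dimensions.
#'
#' @param n_peptides,n_samples matrix dimensions.
#' @param n_missing number of missing entries.
#' @return list with `total_observations`, `n_observed`, `pct_missing`
#'   (1-decimal).
#' @export
dataset_accounting <- function(n_peptides, n_samples, n_missing) {
  total <- n_peptides * n_samples
  if (n_missing < 0 || n_missing > total) stop("invalid missing count")
  list(total_observations = total,
       n_observed = total - n_missing,
       pct_missing = round(100 * n_missing / total, 1))
}

#' Minimum-coverage filter on observed measurements per group
#'
#' Retains a peptide only if its count of OBSERVED (non-imputed) values is
#' at least `min_samples` in the control group AND at least `min_samples`
#' in the cancer group. Imputed cells never count toward coverage: the
#' missing mask survives imputation precisely so the filter can act on
#' direct measurements only. Row order of retained peptides is preserved.
#'
#' @param table a completed [peptide_table] (post-imputation).
#' @param labels [group_labels] covering every column.
#' @param imputed_mask logical matrix marking imputed cells (from
#'   [impute_minprob()]).
#' @param min_samples per-group coverage threshold; must not exceed either
#'   group size.
#' @return list with `table` (filtered [peptide_table]) and `report`
#'   ([filter_report]).
#' @export
filter_min_samples <- function(table, labels, imputed_mask, min_samples) {
  stopifnot(inherits(table, "peptide_table"))
  y <- check_labels(table, labels)
  if (!is.matrix(imputed_mask) ||
      !identical(dim(imputed_mask), dim(table$intensity)))
    stop("'imputed_mask' must be a logical matrix matching the table")
  n_ctrl <- sum(y == 0L); n_case <- sum(y == 1L)
  if (min_samples < 0) stop("'min_samples' must be non-negative")
  if (min_samples > min(n_ctrl, n_case))
    stop(sprintf("min_samples = %d exceeds a group size (control %d, cancer %d)",
                 min_samples, n_ctrl, n_case))
  obs <- !imputed_mask
  obs_ctrl <- rowSums(obs[, y == 0L, drop = FALSE])
  obs_case <- rowSums(obs[, y == 1L, drop = FALSE])
  keep <- obs_ctrl >= min_samples & obs_case >= min_samples

  rep <- filter_report(
    min_samples = min_samples, n_samples = ncol(table$intensity),
    removed_peptides = sum(!keep), retained_peptides = sum(keep),
    removed_values_observed = sum(obs[!keep, , drop = FALSE]),
    removed_values_imputed = sum(imputed_mask[!keep, , drop = FALSE]),
    retained_values_observed = sum(obs[keep, , drop = FALSE]),
    retained_values_imputed = sum(imputed_mask[keep, , drop = FALSE]))

  out <- table
  out$intensity <- table$intensity[keep, , drop = FALSE]
  out$meta <- table$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  list(table = out, report = rep)
}

#' Collapse duplicate peptide rows by averaging
#'
#' Rows sharing an identical peptide sequence (verbatim, including
#' flanking-dot notation) are merged into a single row whose per-sample
#' values are the arithmetic mean on the working (log2) scale. Metadata are
#' taken from the first occurrence in input order, and output rows keep the
#' order of first occurrences. Collapsing is idempotent.
#'
#' @param table a completed [peptide_table] (no missing values).
#' @return A [peptide_table] with one row per distinct peptide sequence.
#' @export
collapse_duplicates <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  if (anyNA(table$intensity))
    stop("collapse_duplicates requires a completed (imputed) table")
  key <- table$meta$peptide
  first <- !duplicated(key)
  if (all(first)) return(table)
  f <- factor(key, levels = key[first])
  summed <- rowsum(table$intensity, f, reorder = FALSE)
  counts <- as.vector(table(f))
  out <- table
  out$intensity <- summed / counts
  colnames(out$intensity) <- colnames(table$intensity)
  out$meta <- table$meta[first, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Histogram data for observed vs imputed intensities per sample
#'
#' Shared-bin histogram counts of observed and imputed values for each
#' sample, as plot-ready data for before/after imputation displays.
#'
#' @param table completed [peptide_table].
#' @param imputed_mask logical matrix from [impute_minprob()].
#' @param breaks number of bins (passed to [pretty()] over the value range).
#' @return data.frame with `sample_id`, `bin_lower`, `bin_upper`,
#'   `n_observed`, `n_imputed`.
#' @export
intensity_histograms <- function(table, imputed_mask, breaks = 30) {
  stopifnot(inherits(table, "peptide_table"))
  x <- table$intensity
  edges <- pretty(range(x), n = breaks)
  res <- lapply(colnames(x), function(s) {
    v <- x[, s]
    m <- imputed_mask[, s]
    ho <- graphics::hist(v[!m], breaks = edges, plot = FALSE)
    hi <- if (any(m)) graphics::hist(v[m], breaks = edges, plot = FALSE)$counts
    else rep(0L, length(ho$counts))
    data.frame(sample_id = s, bin_lower = utils::head(edges, -1),
               bin_upper = edges[-1], n_observed = ho$counts,
               n_imputed = hi)
  })
  do.call(rbind, res)
}
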