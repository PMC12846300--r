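#' Empirical case CDF over intensity-sorted positions
#'
#' Sorts the samples by ascending peptide intensity (stable: ties keep the
#' original sample order) and returns, at each sorted position j, the
#' cumulative fraction of cancer labels among the first j positions. By
#' construction the curve is nondecreasing and reaches exactly 1 at j = n.
#' It depends on the intensities only through their ordering, so any
#' strictly increasing transform leaves it unchanged.
#'
#' @param values numeric vector of per-sample intensities (no missing).
#' @param labels binary vector (1 = cancer) aligned with `values`, or a
#'   [group_labels] vector named by `names(values)`.
#' @return numeric vector `cdf` of length `n`.
#' @export
empirical_case_cdf <- function(values, labels) {
  y <- align_y(values, labels)
  if (length(values) < 2) stop("need at least 2 samples")
  if (sum(y) == 0) stop("undefined statistic: no cancer samples")
  ys <- y[order(values)]          # order() is stable for ties
  cumsum(ys) / sum(ys)
}

align_y <- function(values, labels) {
  if (inherits(labels, "group_labels") && !is.null(names(values)))
    labels <- unclass(labels)[names(values)]
  y <- as.integer(unclass(labels))
  if (length(y) != length(values) || anyNA(y))
    stop("labels must align with values")
  y
}

# Mean/SD of surrogate CDFs at each sorted position, under label shuffling.
# The null depends only on the label multiset, never on the intensities, so
# one set of surrogates serves a whole table.
surrogate_moments <- function(y, B = 1000, seed = 1L, exact_mode = FALSE) {
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0 || n1 == n) stop("undefined statistic: constant labels")
  if (exact_mode) {
    idx <- utils::combn(n, n1)
    cdfs <- apply(idx, 2, function(i) {
      yy <- integer(n); yy[i] <- 1L
      cumsum(yy) / n1
    })
  } else {
    if (B < 1) stop("B must be at least 1")
    set.seed(seed)
    cdfs <- replicate(B, cumsum(sample(y)) / n1)
  }
  mu <- rowMeans(cdfs)
  nb <- ncol(cdfs)
  sdv <- sqrt(rowSums((cdfs - mu)^2) / (nb - 1))
  list(mu = mu, sd = sdv, n_surrogates = nb)
}

#' Permutation CDF deviation statistic S for one peptide
#'
#' The S statistic is the maximum, over intensity-sorted positions j, of
#' the absolute deviation between the observed case CDF and its
#' permutation-null mean, in units of the null standard deviation:
#' `S = max_j |CDF_real(j) - mu_surrogate(j)| / sigma_surrogate(j)`.
#' The null is built by shuffling the class labels over the fixed intensity
#' ordering, either by `B` uniform random shuffles (the real labeling may
#' reappear and is not excluded) or, with `exact_mode = TRUE`, by
#' enumerating every distinct assignment of the label multiset once.
#'
#' Positions where the null SD falls below `sigma_floor` are skipped: at
#' j = n every CDF equals 1, so both the numerator and the SD vanish and
#' the ratio is vacuous.
#'
#' @inheritParams empirical_case_cdf
#' @param B number of permutation surrogates (default 1000); ignored in
#'   exact mode.
#' @param seed RNG seed for the shuffles.
#' @param exact_mode enumerate all `choose(n, n1)` label assignments
#'   instead of sampling.
#' @param sigma_floor smallest null SD treated as nonzero.
#' @return The scalar S (>= 0).
#' @export
s_statistic <- function(values, labels, B = 1000, seed = 1L,
                        exact_mode = FALSE, sigma_floor = 1e-12) {
  y <- align_y(values, labels)
  if (sigma_floor <= 0) stop("sigma_floor must be positive")
  cdf_real <- empirical_case_cdf(values, y)
  mom <- surrogate_moments(y, B = B, seed = seed, exact_mode = exact_mode)
  keep <- mom$sd >= sigma_floor
  if (!any(keep)) stop("degenerate null: all positions have zero surrogate SD")
  max(abs(cdf_real - mom$mu)[keep] / mom$sd[keep])
}

#' Classify S values into significance bands
#'
#' Fixed cutpoints: `high` for S >= 3, `moderate` for 2 <= S < 3, `low`
#' for 1 <= S < 2, `nonsignificant` for S < 1. S is expressed in null-SD
#' units, so the bands read as 1, 2, 3 standard deviations from the
#' permutation null.
#'
#' @param S numeric vector of S statistics (>= 0).
#' @return factor with levels `high`, `moderate`, `low`, `nonsignificant`.
#' @export
classify_band <- function(S) {
  if (any(S < 0, na.rm = TRUE)) stop("S must be non-negative")
  cut(S, breaks = c(-Inf, 1, 2, 3, Inf), right = FALSE,
      labels = c("nonsignificant", "low", "moderate", "high")) |>
    factor(levels = c("high", "moderate", "low", "nonsignificant"))
}

#' Table-wide CDF significance analysis
#'
#' Computes S and its band for every peptide of a completed, collapsed
#' table. One set of permutation surrogates is shared across peptides: the
#' null distribution of the surrogate CDFs depends only on the label
#' multiset, not on any peptide's intensities, so sharing changes nothing
#' statistically and keeps the run reproducible from a single seed.
#'
#' @param table completed [peptide_table] (log2 scale, no missing values).
#' @param labels [group_labels].
#' @inheritParams s_statistic
#' @return data.frame of class `cdf_result` with columns `peptide`,
#'   `protein_id`, `S`, `band`; the permutation configuration is attached
#'   as attribute `config`.
#' @export
cdf_significance <- function(table, labels, B = 1000, seed = 1L,
                             exact_mode = FALSE, sigma_floor = 1e-12) {
  stopifnot(inherits(table, "peptide_table"))
  if (anyNA(table$intensity))
    stop("cdf_significance requires a completed (imputed) table")
  y <- check_labels(table, labels)
  mom <- surrogate_moments(y, B = B, seed = seed, exact_mode = exact_mode)
  keep <- mom$sd >= sigma_floor
  if (!any(keep)) stop("degenerate null: all positions have zero surrogate SD")
  n1 <- sum(y)
  S <- apply(table$intensity, 1, function(x) {
    cdf_real <- cumsum(y[order(x)]) / n1
    max(abs(cdf_real - mom$mu)[keep] / mom$sd[keep])
  })
  res <- data.frame(peptide = table$meta$peptide,
                    protein_id = table$meta$protein_id,
                    S = unname(S),
                    band = classify_band(unname(S)),
                    stringsAsFactors = FALSE)
  attr(res, "config") <- list(B = mom$n_surrogates, seed = seed,
                              exact_mode = exact_mode,
                              sigma_floor = sigma_floor)
  class(res) <- c("cdf_result", "data.frame")
  res
}

#' Band census of a peptide set
#'
#' Counts and percentages per significance band, plus the counts above the
#' S = 2 and S = 1 thresholds. Because "exceeding" a threshold is ambiguous
#' exactly at the cutpoint, both conventions are reported when numeric S
#' values are supplied: `n_gt_2` / `n_gt_1` count strictly greater,
#' `n_ge_2` / `n_ge_1` count greater-or-equal. Under the banding
#' convention, high + moderate equals the `n_ge_2` count.
#'
#' @param x a `cdf_result`, a numeric vector of S values, or a
#'   factor/character vector of band labels.
#' @return list of class `band_census` with `n_total`, `counts`,
#'   `percentages` (1-decimal), `n_gt_2`, `n_ge_2`, `n_gt_1`, `n_ge_1`
#'   (threshold counts are `NA` when only band labels are supplied, except
#'   the band-derived `n_ge_*`).
#' @export
band_census <- function(x) {
  s <- NULL
  if (inherits(x, "cdf_result")) s <- x$S
  else if (is.numeric(x)) s <- x
  bands <- if (!is.null(s)) classify_band(s)
  else factor(as.character(x),
              levels = c("high", "moderate", "low", "nonsignificant"))
  if (!length(bands)) stop("empty result set")
  if (anyNA(bands)) stop("unknown band label")
  counts <- table(bands)
  n <- length(bands)
  structure(list(
    n_total = n,
    counts = stats::setNames(as.integer(counts), names(counts)),
    percentages = stats::setNames(round(100 * as.integer(counts) / n, 1),
                                  names(counts)),
    n_gt_2 = if (!is.null(s)) sum(s > 2) else NA_integer_,
    n_ge_2 = if (!is.null(s)) sum(s >= 2)
             else sum(counts[c("high", "moderate")]),
    n_gt_1 = if (!is.null(s)) sum(s > 1) else NA_integer_,
    n_ge_1 = if (!is.null(s)) sum(s >= 1)
             else sum(counts[c("high", "moderate", "low")])
  ), class = "band_census")
}

#' @export
print.band_census <- function(x, ...) {
  cat(sprintf("band census of %d peptides\n", x$n_total))
  for (b in names(x$counts))
    cat(sprintf("  %-15s %4d (%.1f%%)\n", b, x$counts[[b]],
                x$percentages[[b]]))
  cat(sprintf("  S > 2: %s   S >= 2: %d\n",
              ifelse(is.na(x$n_gt_2), "-", x$n_gt_2), x$n_ge_2))
  invisible(x)
}
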