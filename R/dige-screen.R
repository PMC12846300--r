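#' Screen 2D-DIGE master spots by presence, significance and fold change
#'
#' A spot is selected when all three clauses hold: it was matched in at
#' least `min_presence` of `n_gels` gels, its per-spot two-sample test has
#' `p < alpha`, and its differential expression passes the fold-change
#' clause. Average ratios follow the DeCyder signed-linear convention
#' (+r means r-fold up in patients, -r means r-fold down; magnitudes below
#' 1 do not occur), so the default fold clause is `|av_ratio| >=
#' fold_threshold`, a true `fold_threshold`-fold change. With
#' `ratio_scale = "log2"` the clause is instead
#' `|log2(|av_ratio|)| >= fold_threshold`.
#'
#' @param spots data.frame with columns `master_no`, `presence_count`,
#'   `p_value`, `av_ratio` (and optionally `match_quality`), e.g. from
#'   [generate_spot_table()].
#' @param n_gels gels in the experiment (default 33).
#' @param min_presence minimum gels containing the spot (default 24).
#' @param alpha significance level (default 0.05, strict inequality).
#' @param fold_threshold minimal fold change (default 2).
#' @param ratio_scale thresholding convention for the fold clause.
#' @return list with `selected` (passing subset) and `detail` (`spots`
#'   plus logical columns `pass_presence`, `pass_pvalue`, `pass_fold`,
#'   `selected`, and a `reasons` string naming the failed clauses).
#' @export
screen_spots <- function(spots, n_gels = 33, min_presence = 24,
                         alpha = 0.05, fold_threshold = 2,
                         ratio_scale = c("signed_linear", "log2")) {
  ratio_scale <- match.arg(ratio_scale)
  if (min_presence > n_gels) stop("min_presence cannot exceed n_gels")
  if (fold_threshold < 0) stop("fold_threshold must be non-negative")
  if (nrow(spots) &&
      (any(spots$presence_count < 0 | spots$presence_count > n_gels)))
    stop("presence counts must lie in [0, n_gels]")
  mag <- abs(spots$av_ratio)
  pass_fold <- if (ratio_scale == "signed_linear") mag >= fold_threshold
  else abs(log2(mag)) >= fold_threshold
  detail <- spots
  detail$pass_presence <- spots$presence_count >= min_presence
  detail$pass_pvalue <- spots$p_value < alpha
  detail$pass_fold <- pass_fold
  detail$selected <- detail$pass_presence & detail$pass_pvalue &
    detail$pass_fold
  detail$reasons <- vapply(seq_len(nrow(detail)), function(i) {
    fails <- c("presence", "p_value", "fold")[
      !c(detail$pass_presence[i], detail$pass_pvalue[i],
         detail$pass_fold[i])]
    if (length(fails)) paste(fails, collapse = ",") else ""
  }, character(1))
  list(selected = spots[detail$selected, , drop = FALSE], detail = detail)
}

#' Two-sample t-test p-value for a spot's volumes
#'
#' Two-sided Student t-test with pooled variance by default (`welch =
#' TRUE` switches to the Welch form). If both groups are exactly constant,
#' the p-value is 1 when the means agree and 0 when they differ (the
#' degenerate limit of the statistic).
#'
#' @param group1,group2 numeric spot volumes, at least 2 values each.
#' @param welch use the Welch (unequal-variance) form.
#' @return two-sided p-value.
#' @export
spot_t_test <- function(group1, group2, welch = FALSE) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0)
    return(if (mean(group1) == mean(group2)) 1 else 0)
  stats::t.test(group1, group2, var.equal = !welch)$p.value
}

#' Volcano-plot coordinates for a spot table
#'
#' x = signed log2 fold magnitude (`sign(av_ratio) * log2(|av_ratio|)`),
#' y = -log10(p). Zero p-values are clipped to the smallest positive
#' double and flagged. `match_quality` is passed through as a size field.
#'
#' @param spots data.frame as in [screen_spots()].
#' @return data.frame with `master_no`, `log2_ratio`, `neg_log10_p`,
#'   `size`, `p_clipped`.
#' @export
volcano_coordinates <- function(spots) {
  p <- spots$p_value
  clipped <- p <= 0
  p[clipped] <- .Machine$double.xmin
  data.frame(
    master_no = spots$master_no,
    log2_ratio = sign(spots$av_ratio) * log2(abs(spots$av_ratio)),
    neg_log10_p = -log10(p),
    size = if ("match_quality" %in% names(spots)) spots$match_quality
    else NA_real_,
    p_clipped = clipped)
}

#' Dual-parameter confidence prioritization of identified proteins
#'
#' Classifies each identified protein as high- or moderate-confidence by
#' comparing its identification score against a threshold placed at the
#' lower third of the score distribution (the inclusive lower-third order
#' statistic, `sort(score)[ceiling(n/3)]`; scores at or above the
#' threshold are high-confidence). Emits plot-ready coordinates: score vs
#' signed average ratio, with peptide count as the size field.
#'
#' @param maldi_table data.frame as from [read_maldi_table()].
#' @param score_field which identification score to use.
#' @return data.frame with `protein_id`, `score`, `av_ratio`, `pep_count`,
#'   `confidence`; the threshold is attached as attribute `threshold`.
#' @export
dual_parameter_prioritize <- function(maldi_table,
                                      score_field = c("hit_score",
                                                      "protein_score")) {
  score_field <- match.arg(score_field)
  if (nrow(maldi_table) < 3)
    stop("need at least 3 records to define a tertile threshold")
  if (!score_field %in% names(maldi_table))
    stop("score field '", score_field, "' not present")
  score <- maldi_table[[score_field]]
  threshold <- sort(score)[ceiling(length(score) / 3)]
  out <- data.frame(
    protein_id = maldi_table$protein_id,
    score = score,
    av_ratio = maldi_table$av_ratio,
    pep_count = if ("pep_count" %in% names(maldi_table))
      maldi_table$pep_count else NA_integer_,
    confidence = ifelse(score >= threshold, "high", "moderate"),
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}
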