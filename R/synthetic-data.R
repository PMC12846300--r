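#' Specification of a synthetic case-control cohort
#'
#' Describes the generative model used by [generate_cohort()]: per-peptide
#' normal baselines on the log2 scale, an additive class shift for a
#' configurable subset of truly differential peptides, and an
#' intensity-dependent logistic dropout that censors low-abundance
#' measurements (missing-not-at-random, the mechanism left-censored
#' imputation assumes).
#'
#' Defaults emulate the dimensions of a small serum LC-MS/MS discovery
#' cohort: 286 peptide entries across 12 samples (6 control, 6 cancer) with
#' roughly 19% of entries missing, concentrated at low intensities. The
#' dropout curve `P(missing | x) = plogis(steepness * (midpoint - x))` with
#' midpoint 17.5 and steepness 1 yields an expected missing fraction of
#' about 0.19 under the default intensity distribution (baseline means
#' N(20, 2), within-peptide noise SD 1).
#'
#' @param n_peptides number of distinct peptides.
#' @param n_control,n_cancer samples per class.
#' @param frac_differential fraction of peptides that are truly differential.
#' @param effect_size_log2 log2-intensity shift added to differential
#'   peptides in the cancer class.
#' @param base_mean_log2,base_sd_log2 mean and SD of the per-peptide baseline
#'   log2 intensity.
#' @param noise_sd_log2 within-peptide (sample-to-sample) SD on the log2
#'   scale.
#' @param dropout_midpoint_log2 log2 intensity at which dropout probability
#'   is 0.5.
#' @param dropout_steepness slope of the logistic dropout curve; `Inf`
#'   disables stochastic dropout below/above the midpoint.
#' @param n_duplicate_rows number of peptide entries duplicated across rows
#'   (to exercise collapsing).
#' @param n_proteins number of distinct precursor accessions.
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_peptides = 286, n_control = 6, n_cancer = 6,
                        frac_differential = 0.1, effect_size_log2 = 2,
                        base_mean_log2 = 20, base_sd_log2 = 2,
                        noise_sd_log2 = 1,
                        dropout_midpoint_log2 = 17.5, dropout_steepness = 1,
                        n_duplicate_rows = 20, n_proteins = 22,
                        seed = 1L) {
  if (n_peptides < 1 || n_control < 1 || n_cancer < 1)
    stop("invalid cohort spec: dimensions must be positive")
  if (frac_differential < 0 || frac_differential > 1)
    stop("invalid cohort spec: frac_differential must lie in [0, 1]")
  if (n_duplicate_rows < 0 || n_proteins < 1)
    stop("invalid cohort spec: counts must be non-negative")
  structure(list(
    n_peptides = as.integer(n_peptides),
    n_control = as.integer(n_control), n_cancer = as.integer(n_cancer),
    frac_differential = frac_differential,
    effect_size_log2 = effect_size_log2,
    base_mean_log2 = base_mean_log2, base_sd_log2 = base_sd_log2,
    noise_sd_log2 = noise_sd_log2,
    dropout_midpoint_log2 = dropout_midpoint_log2,
    dropout_steepness = dropout_steepness,
    n_duplicate_rows = as.integer(n_duplicate_rows),
    n_proteins = as.integer(n_proteins),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# dropout probability as a function of log2 intensity; decreasing in x
dropout_prob <- function(x, midpoint, steepness) {
  if (is.infinite(steepness)) return(as.numeric(x < midpoint))
  stats::plogis(steepness * (midpoint - x))
}

#' Generate a synthetic peptide cohort with MNAR dropout
#'
#' Draws a log2 intensity matrix under the model described in
#' [cohort_spec()], censors entries with intensity-dependent probability,
#' appends duplicate peptide rows (same sequence and accession,
#' independently drawn intensities) and returns the table, the sample
#' labels, and the ground-truth differential flags for parameter-recovery
#' testing. Fully reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec].
#' @return A list with elements `table` ([peptide_table], log2 scale, `NA`
#'   for missing), `labels` ([group_labels]), `truth` (data.frame with
#'   `peptide`, `protein_id`, `differential` flag, one row per distinct
#'   peptide), and `latent` (the uncensored intensity matrix, for checking
#'   the dropout mechanism).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- spec$n_peptides
  n <- spec$n_control + spec$n_cancer
  sample_id <- c(sprintf("ctrl_%02d", seq_len(spec$n_control)),
                 sprintf("case_%02d", seq_len(spec$n_cancer)))
  y <- c(rep(0L, spec$n_control), rep(1L, spec$n_cancer))

  pep_seq <- sprintf("K.PEP%04dSYNR.V", seq_len(p))
  prot <- sprintf("SYN%03d|SYNP%03d_HUMAN",
                  ((seq_len(p) - 1L) %% spec$n_proteins) + 1L,
                  ((seq_len(p) - 1L) %% spec$n_proteins) + 1L)
  n_diff <- round(spec$frac_differential * p)
  differential <- seq_len(p) <= n_diff   # first block is differential

  base_mu <- stats::rnorm(p, spec$base_mean_log2, spec$base_sd_log2)
  mu_mat <- matrix(base_mu, p, n)
  shift <- outer(ifelse(differential, spec$effect_size_log2, 0), y)
  x <- mu_mat + shift + matrix(stats::rnorm(p * n, 0, spec$noise_sd_log2),
                               p, n)

  # duplicate rows: resampled intensities around the same peptide baseline
  dup_idx <- if (spec$n_duplicate_rows > 0)
    sample(p, spec$n_duplicate_rows, replace = spec$n_duplicate_rows > p)
  else integer(0)
  if (length(dup_idx)) {
    xd <- mu_mat[dup_idx, , drop = FALSE] + shift[dup_idx, , drop = FALSE] +
      matrix(stats::rnorm(length(dup_idx) * n, 0, spec$noise_sd_log2),
             length(dup_idx), n)
    x <- rbind(x, xd)
  }
  latent <- x
  miss <- matrix(stats::runif(length(x)), nrow(x), ncol(x)) <
    dropout_prob(x, spec$dropout_midpoint_log2, spec$dropout_steepness)
  x[miss] <- NA_real_
  colnames(x) <- colnames(latent) <- sample_id

  tab <- peptide_table(x,
                       peptide = c(pep_seq, pep_seq[dup_idx]),
                       protein_id = c(prot, prot[dup_idx]),
                       flank_context = NA_character_,
                       scale = "log2")
  list(table = tab,
       labels = group_labels(y, sample_id),
       truth = data.frame(peptide = pep_seq, protein_id = prot,
                          differential = differential,
                          stringsAsFactors = FALSE),
       latent = latent)
}

#' Build a table with an exactly specified coverage profile
#'
#' Constructs a peptide table whose per-peptide, per-group observed counts
#' match `profile` exactly, for deterministic testing of the coverage
#' filter's accounting. Observed cells get arbitrary finite log2 values.
#'
#' @param profile data.frame (or 2-column matrix) with columns
#'   `n_obs_control` and `n_obs_cancer`, one row per peptide.
#' @param n_control,n_cancer group sizes.
#' @param seed RNG seed for the (arbitrary) observed values.
#' @return A list with `table` ([peptide_table]) and `labels`
#'   ([group_labels]).
#' @export
generate_filter_fixture <- function(profile, n_control = 6, n_cancer = 6,
                                    seed = 1L) {
  profile <- as.data.frame(profile)
  if (!all(c("n_obs_control", "n_obs_cancer") %in% names(profile)))
    stop("profile needs columns 'n_obs_control' and 'n_obs_cancer'")
  if (any(profile$n_obs_control < 0) || any(profile$n_obs_cancer < 0) ||
      any(profile$n_obs_control > n_control) ||
      any(profile$n_obs_cancer > n_cancer))
    stop("invalid profile: observed counts must lie in [0, group size]")
  set.seed(seed)
  p <- nrow(profile)
  n <- n_control + n_cancer
  x <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    oc <- profile$n_obs_control[i]
    oa <- profile$n_obs_cancer[i]
    if (oc > 0) x[i, seq_len(oc)] <- 20 + stats::rnorm(oc)
    if (oa > 0) x[i, n_control + seq_len(oa)] <- 20 + stats::rnorm(oa)
  }
  sample_id <- c(sprintf("ctrl_%02d", seq_len(n_control)),
                 sprintf("case_%02d", seq_len(n_cancer)))
  colnames(x) <- sample_id
  list(table = peptide_table(x,
                             peptide = sprintf("K.FIX%04dR.A", seq_len(p)),
                             protein_id = sprintf("FIX%03d|FIX_HUMAN",
                                                  seq_len(p)),
                             scale = "log2"),
       labels = group_labels(c(rep(0L, n_control), rep(1L, n_cancer)),
                             sample_id))
}

#' Generate a random 2D-DIGE master-spot table
#'
#' Random spot records on the scale of a DIGE screen: presence counts in
#' `[1, n_gels]`, p-values in (0, 1), signed linear average ratios with
#' magnitude at least 1 (DeCyder convention), and match-quality scores.
#'
#' @param n_spots number of master spots.
#' @param n_gels number of gels in the experiment.
#' @param seed RNG seed.
#' @return data.frame with columns `master_no`, `presence_count`, `p_value`,
#'   `av_ratio`, `match_quality`.
#' @export
generate_spot_table <- function(n_spots, n_gels = 33, seed = 1L) {
  if (n_gels < 1) stop("n_gels must be at least 1")
  if (n_spots < 0) stop("n_spots must be non-negative")
  set.seed(seed)
  if (n_spots == 0)
    return(data.frame(master_no = integer(0), presence_count = integer(0),
                      p_value = numeric(0), av_ratio = numeric(0),
                      match_quality = numeric(0)))
  data.frame(
    master_no = seq_len(n_spots),
    presence_count = sample.int(n_gels, n_spots, replace = TRUE),
    p_value = stats::runif(n_spots, 1e-6, 1 - 1e-6),
    av_ratio = sample(c(-1, 1), n_spots, replace = TRUE) *
      (1 + stats::rexp(n_spots, rate = 0.5)),
    match_quality = stats::runif(n_spots)
  )
}
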