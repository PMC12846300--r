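#' Pipeline configuration
#'
#' Bundles all stage parameters plus a single master seed. Stage seeds are
#' derived deterministically from the master seed and the stage name, so
#' adding a stage never perturbs the randomness of earlier stages.
#'
#' @param out_dir directory for stage outputs (created if absent).
#' @param cohort a [cohort_spec] used when no input table is supplied.
#' @param downshift,width left-censored imputation parameters.
#' @param min_samples per-group coverage threshold.
#' @param B permutation surrogates for the CDF stage.
#' @param n_trees trees per LOOCV forest.
#' @param probability_threshold cancer-call cutoff.
#' @param s_threshold protein-rollup significance threshold on S.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_spec(),
                            downshift = 1.8, width = 0.3, min_samples = 4,
                            B = 1000, n_trees = 100,
                            probability_threshold = 0.5, s_threshold = 2,
                            seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 downshift = downshift, width = width,
                 min_samples = min_samples, B = B, n_trees = n_trees,
                 probability_threshold = probability_threshold,
                 s_threshold = s_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

# stable stage seed: depends only on (master seed, stage name)
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 1009 + h * 31) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order: (simulate or ingest) -> impute ->
#' filter -> collapse -> CDF significance and RF LOOCV -> protein
#' aggregation -> report, writing every stage output as TSV/YAML to the
#' run directory together with a provenance manifest (parameters, derived
#' stage seeds, per-stage counts, output checksums, package version).
#' Rerunning with an identical configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config].
#' @param table optional input [peptide_table]; when `NULL`, a synthetic
#'   cohort is generated from `cfg$cohort`.
#' @param labels [group_labels]; required with `table`.
#' @param maldi_table optional MALDI identification data.frame for
#'   protein-level cross-validation.
#' @return invisible list with all stage results (`table_raw`,
#'   `imputation`, `filter`, `collapsed`, `cdf`, `census`, `rf`,
#'   `proteins`, `strong`, `manifest_file`, `out_dir`).
#' @export
run_pipeline <- function(cfg, table = NULL, labels = NULL,
                         maldi_table = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(table)) {
    gen <- generate_cohort(cfg$cohort)
    table <- gen$table
    labels <- gen$labels
  } else if (is.null(labels)) stop("labels are required with an input table")
  y <- check_labels(table, labels)
  if (cfg$min_samples > min(sum(y == 0), sum(y == 1)))
    stop("configuration error: min_samples exceeds a group size")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (table$scale == "linear") table <- to_log2(table)
  imp <- impute_minprob(table, downshift = cfg$downshift, width = cfg$width,
                        seed = stage_seed(cfg$seed, "impute"))
  flt <- filter_min_samples(imp$table, labels, imp$imputed_mask,
                            cfg$min_samples)
  collapsed <- collapse_duplicates(flt$table)

  cdf <- cdf_significance(collapsed, labels, B = cfg$B,
                          seed = stage_seed(cfg$seed, "cdf"))
  census <- band_census(cdf)
  rf <- loocv_rf(collapsed, labels, n_trees = cfg$n_trees,
                 seed = stage_seed(cfg$seed, "rf"),
                 probability_threshold = cfg$probability_threshold)
  prot <- aggregate_proteins(cdf, s_threshold = cfg$s_threshold)
  if (!is.null(maldi_table)) prot <- cross_validate_maldi(prot, maldi_table)
  strong <- prot[prot$strong_evidence, , drop = FALSE]

  p <- function(f) file.path(cfg$out_dir, f)
  write_peptide_table(collapsed, p("collapsed.tsv"))
  write_sample_sheet(labels, p("samples.tsv"))
  utils::write.table(as.data.frame(cdf), p("cdf_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rf$predictions, p("rf_predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rf$importance, p("rf_importance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rf$roc, p("rf_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(prot), p("protein_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass_deep(flt$report), p("filter_report.yaml"))
  yaml::write_yaml(unclass_deep(census), p("band_census.yaml"))

  outputs <- c("collapsed.tsv", "samples.tsv", "cdf_results.tsv",
               "rf_predictions.tsv", "rf_importance.tsv", "rf_roc.tsv",
               "protein_summary.tsv", "filter_report.yaml",
               "band_census.yaml")
  manifest <- list(
    package_version = as.character(utils::packageVersion("serumsig")),
    master_seed = cfg$seed,
    stage_seeds = list(impute = stage_seed(cfg$seed, "impute"),
                       cdf = stage_seed(cfg$seed, "cdf"),
                       rf = stage_seed(cfg$seed, "rf")),
    parameters = list(downshift = cfg$downshift, width = cfg$width,
                      min_samples = cfg$min_samples, B = cfg$B,
                      n_trees = cfg$n_trees,
                      probability_threshold = cfg$probability_threshold,
                      s_threshold = cfg$s_threshold),
    counts = list(peptides_in = flt$report$n_peptides_in,
                  peptides_after_filter = flt$report$retained_peptides,
                  peptides_after_collapse = nrow(collapsed$intensity),
                  proteins = nrow(prot),
                  strong_evidence_proteins = nrow(strong)),
    checksums = as.list(tools::md5sum(file.path(cfg$out_dir, outputs))))
  names(manifest$checksums) <- outputs
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(list(table_raw = table, imputation = imp, filter = flt,
                 collapsed = collapsed, cdf = cdf, census = census,
                 rf = rf, proteins = prot, strong = strong,
                 manifest_file = p("manifest.yaml"),
                 out_dir = cfg$out_dir))
}

# strip S3 classes recursively so yaml serializes plainly
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep)
  else if (is.factor(x)) as.character(x)
  else if (!is.null(names(x))) as.list(x)
  else x
}

#' Render a human-readable run report
#'
#' Reads the stage outputs of a completed [run_pipeline()] directory and
#' writes `report.txt`: band census, protein evidence table, confusion
#' summary, and the top-k concordance between the S and mean-Gini
#' rankings. Rendering is idempotent and fails with a clear message when a
#' stage output is missing.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @param k top-list size for the concordance section.
#' @return path of the report file, invisibly.
#' @export
render_report <- function(run_dir, k = 20) {
  need <- c("cdf_results.tsv", "protein_summary.tsv", "rf_predictions.tsv",
            "rf_importance.tsv", "band_census.yaml")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run directory; missing: ",
         paste(missing, collapse = ", "))
  cdf <- utils::read.delim(file.path(run_dir, "cdf_results.tsv"),
                           stringsAsFactors = FALSE)
  prot <- utils::read.delim(file.path(run_dir, "protein_summary.tsv"),
                            stringsAsFactors = FALSE)
  pred <- utils::read.delim(file.path(run_dir, "rf_predictions.tsv"),
                            stringsAsFactors = FALSE)
  imp <- utils::read.delim(file.path(run_dir, "rf_importance.tsv"),
                           stringsAsFactors = FALSE)
  census <- yaml::read_yaml(file.path(run_dir, "band_census.yaml"))

  k <- min(k, nrow(cdf))
  conc <- rank_concordance(stats::setNames(cdf$S, cdf$peptide),
                           stats::setNames(imp$mean_gini, imp$peptide),
                           k = k)
  strong <- prot[prot$strong_evidence %in% c(TRUE, "TRUE"), , drop = FALSE]

  lines <- c(
    "serum biomarker pipeline report",
    "===============================",
    "",
    sprintf("peptides analysed: %d", nrow(cdf)),
    "",
    "significance band census:",
    vapply(names(census$counts), function(b)
      sprintf("  %-15s %4d (%.1f%%)", b, census$counts[[b]],
              census$percentages[[b]]), character(1)),
    sprintf("  S > 2: %d", census$n_gt_2),
    "",
    "protein evidence (strong-evidence proteins):",
    if (nrow(strong)) vapply(seq_len(nrow(strong)), function(i)
      sprintf("  %s  n_S=%d/%d  ratio=%s  S_max=%.4f", strong$protein_id[i],
              strong$n_peptides_S[i], strong$n_peptides_total[i],
              format(strong$ratio_peptides_S[i]), strong$S_max_peptides[i]),
      character(1))
    else "  none",
    "",
    "confusion summary:",
    vapply(c("TP", "TN", "FP", "FN"), function(cat)
      sprintf("  %s: %d", cat, sum(pred$category == cat)), character(1)),
    "",
    sprintf("ranking concordance (top %d): overlap %d, spearman %.3f",
            conc$k, conc$overlap, conc$spearman))
  out <- file.path(run_dir, "report.txt")
  writeLines(unlist(lines), out)
  invisible(out)
}
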