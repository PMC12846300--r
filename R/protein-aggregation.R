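#' Roll peptide-level S results up to proteins
#'
#' One summary row per distinct protein accession: how many of its peptides
#' exceed the significance threshold (strictly, S > `s_threshold`), how
#' many peptides were detected in total, the percentage of significant
#' peptides, and the maximum peptide S. Two evidence flags are derived:
#' `min_support_met` (at least 2 detected peptides) and `strong_evidence`
#' (at least 2 significant peptides and minimum support).
#'
#' The percentage is computed exactly and rounded to at most three
#' decimals, so recomputing it from the two counts reproduces the printed
#' value (e.g. 9/16 -> 56.25, 2/3 -> 66.667).
#'
#' @param results a `cdf_result` (from [cdf_significance()]) or any
#'   data.frame with columns `peptide`, `protein_id`, `S`. Each peptide
#'   must map to exactly one protein.
#' @param s_threshold significance threshold on S (default 2, exceeded
#'   strictly).
#' @return data.frame of class `protein_summary` with columns `protein_id`,
#'   `n_peptides_S`, `n_peptides_total`, `ratio_peptides_S`,
#'   `S_max_peptides`, `min_support_met`, `strong_evidence`,
#'   `maldi_confirmed` (initialized `NA`; see [cross_validate_maldi()]).
#'   Proteins appear in order of first occurrence.
#' @export
aggregate_proteins <- function(results, s_threshold = 2) {
  req <- c("peptide", "protein_id", "S")
  if (!all(req %in% names(results)))
    stop("'results' needs columns peptide, protein_id, S")
  if (nrow(results) == 0) stop("empty peptide-to-protein mapping")
  multi <- tapply(results$protein_id, results$peptide,
                  function(p) length(unique(p)))
  if (any(multi > 1))
    stop("peptide(s) mapping to multiple proteins: ",
         paste(names(multi)[multi > 1], collapse = ", "))
  prot <- factor(results$protein_id, levels = unique(results$protein_id))
  n_total <- as.integer(table(prot))
  n_sig <- as.integer(tapply(results$S > s_threshold, prot, sum))
  s_max <- as.numeric(tapply(results$S, prot, max))
  out <- data.frame(
    protein_id = levels(prot),
    n_peptides_S = n_sig,
    n_peptides_total = n_total,
    ratio_peptides_S = round(100 * n_sig / n_total, 3),
    S_max_peptides = s_max,
    stringsAsFactors = FALSE)
  out$min_support_met <- out$n_peptides_total >= 2L
  out$strong_evidence <- out$n_peptides_S >= 2L & out$min_support_met
  out$maldi_confirmed <- NA
  class(out) <- c("protein_summary", "data.frame")
  out
}

#' Select strong-evidence proteins
#'
#' Subset of summaries with `strong_evidence == TRUE` (at least two
#' significant peptides and at least two detected peptides), in input
#' order.
#'
#' @param summaries a `protein_summary` data.frame.
#' @return The strong-evidence subset.
#' @export
select_strong_evidence <- function(summaries) {
  if (nrow(summaries) == 0) stop("empty protein summary")
  out <- summaries[summaries$strong_evidence, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-validate protein evidence against a MALDI identification table
#'
#' Flags each summarized protein as MALDI-confirmed when its accession
#' appears in the identification table from the gel-based (2D-DIGE +
#' MALDI-TOF/TOF) arm of the experiment. Accessions are compared verbatim
#' as UniProt `accession|entry` strings.
#'
#' @param summaries a `protein_summary` data.frame.
#' @param maldi_table data.frame with a `protein_id` column (see
#'   [read_maldi_table()]); extra accessions absent from `summaries` are
#'   ignored.
#' @return `summaries` with `maldi_confirmed` set to TRUE/FALSE.
#' @export
cross_validate_maldi <- function(summaries, maldi_table) {
  ids <- if (nrow(maldi_table)) maldi_table$protein_id else character(0)
  summaries$maldi_confirmed <- summaries$protein_id %in% ids
  summaries
}

#' Peptide evidence listing for strong-evidence proteins
#'
#' Lists the member peptides (with flanking-residue context, as stored) of
#' the strong-evidence proteins only, ordered by protein then by input
#' peptide order.
#'
#' @param results data.frame with `peptide`, `protein_id`, `S`, `band`.
#' @param strong_set a `protein_summary` subset (from
#'   [select_strong_evidence()]) or a character vector of accessions; must
#'   be a subset of the proteins in `results`.
#' @return data.frame with `protein_id`, `peptide`, `S`, `band`.
#' @export
peptide_evidence_table <- function(results, strong_set) {
  ids <- if (is.character(strong_set)) strong_set else strong_set$protein_id
  if (!all(ids %in% results$protein_id))
    stop("strong set contains proteins absent from the results")
  out <- do.call(rbind, lapply(ids, function(p)
    results[results$protein_id == p,
            c("protein_id", "peptide", "S", "band")]))
  if (is.null(out))
    out <- results[0, c("protein_id", "peptide", "S", "band")]
  rownames(out) <- NULL
  out
}

#' Read a MALDI-TOF/TOF identification table
#'
#' TSV with columns `protein_id`, `hit_mass`, `hit_score`, `protein_mw`,
#' `protein_pi`, `protein_score`, `pep_count`, `av_ratio`: the Swiss-Prot
#' peptide-mass-fingerprint hit metrics, the NCBInr identification metrics,
#' and the signed DIGE average ratio. A reference copy of the published
#' identification table ships with the package
#' (`system.file("extdata", "maldi_identifications.tsv", package =
#' "serumsig")`).
#'
#' @param file path to the TSV.
#' @return data.frame.
#' @export
read_maldi_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
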