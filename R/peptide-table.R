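#' Peptide-by-sample intensity table
#'
#' The central container of the pipeline: a numeric matrix of peptide
#' intensities (rows = peptide entries, columns = samples) together with
#' per-row metadata and a scale tag. Missing measurements are stored as `NA`;
#' the missing mask is therefore `is.na(intensity)`. The scale tag records
#' whether values are raw (linear) intensities or base-2 logarithms; all
#' statistical stages of the pipeline operate on the log2 scale.
#'
#' @param intensity numeric matrix with column names (sample ids). `NA`
#'   entries mark missing measurements; observed entries must be finite.
#' @param peptide character vector of peptide sequences, one per row.
#'   Sequences are kept verbatim, including flanking-dot notation such as
#'   `"K.AETGDKVYVHLK.N"`.
#' @param protein_id character vector of precursor protein accessions
#'   (e.g. `"P01024|CO3_HUMAN"`), one per row.
#' @param flank_context optional character vector of flanking-residue
#'   context, recycled if length 1.
#' @param scale `"log2"` or `"linear"`.
#'
#' @return An object of class `peptide_table`: a list with elements
#'   `intensity`, `meta` (data.frame with `peptide`, `protein_id`,
#'   `flank_context`) and `scale`.
#' @export
peptide_table <- function(intensity, peptide, protein_id,
                          flank_context = NA_character_,
                          scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("'intensity' must be a numeric matrix")
  if (is.null(colnames(intensity)))
    stop("'intensity' must have sample ids as column names")
  if (anyDuplicated(colnames(intensity)))
    stop("duplicate sample ids in 'intensity' column names")
  if (length(peptide) != nrow(intensity))
    stop("'peptide' length must equal nrow(intensity)")
  if (length(protein_id) != nrow(intensity))
    stop("'protein_id' length must equal nrow(intensity)")
  if (length(flank_context) == 1L)
    flank_context <- rep(flank_context, nrow(intensity))
  obs <- intensity[!is.na(intensity)]
  if (length(obs) && any(!is.finite(obs)))
    stop("observed intensities must be finite")
  structure(
    list(
      intensity = intensity,
      meta = data.frame(peptide = as.character(peptide),
                        protein_id = as.character(protein_id),
                        flank_context = as.character(flank_context),
                        stringsAsFactors = FALSE),
      scale = scale
    ),
    class = "peptide_table"
  )
}

#' @export
print.peptide_table <- function(x, ...) {
  nmiss <- sum(is.na(x$intensity))
  ntot <- length(x$intensity)
  cat(sprintf("peptide_table: %d peptide entries x %d samples [%s scale]\n",
              nrow(x$intensity), ncol(x$intensity), x$scale))
  cat(sprintf("  missing: %d / %d (%.1f%%)\n", nmiss, ntot,
              if (ntot) 100 * nmiss / ntot else 0))
  invisible(x)
}

#' @export
dim.peptide_table <- function(x) dim(x$intensity)

#' Sample class labels for a case-control cohort
#'
#' Builds a named binary label vector mapping sample id to class, with the
#' convention 1 = cancer (case) and 0 = control.
#'
#' @param class integer-like vector of 0/1 class codes.
#' @param sample_id character vector of sample ids (defaults to
#'   `names(class)`).
#' @return Named integer vector of class `group_labels`.
#' @export
group_labels <- function(class, sample_id = names(class)) {
  class <- as.integer(class)
  if (is.null(sample_id)) stop("sample ids are required")
  if (length(sample_id) != length(class))
    stop("'sample_id' and 'class' lengths differ")
  if (!all(class %in% c(0L, 1L))) stop("class labels must be 0 or 1")
  structure(stats::setNames(class, sample_id), class = "group_labels")
}

# Align labels to a table's columns; error if any sample lacks a label or a
# class is empty.
check_labels <- function(table, labels) {
  ids <- colnames(table$intensity)
  if (!all(ids %in% names(labels)))
    stop("samples without class label: ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  y <- as.integer(unclass(labels)[ids])
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("both classes (control and cancer) must be non-empty")
  stats::setNames(y, ids)
}

#' Write / read a peptide table as TSV
#'
#' The on-disk dialect has columns `peptide`, `protein_id`, `flank_context`,
#' then one column per sample id. Missing entries are serialized as empty
#' fields.
#'
#' @param table a [peptide_table].
#' @param file path to a TSV file.
#' @return `write_peptide_table` returns `file` invisibly;
#'   `read_peptide_table` returns a [peptide_table].
#' @export
write_peptide_table <- function(table, file) {
  stopifnot(inherits(table, "peptide_table"))
  df <- cbind(table$meta, as.data.frame(table$intensity, optional = TRUE))
  utils::write.table(df, file, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_peptide_table
#' @param scale scale tag to assign to the values read.
#' @export
read_peptide_table <- function(file, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  meta_cols <- c("peptide", "protein_id", "flank_context")
  if (!all(meta_cols[1:2] %in% names(df)))
    stop("peptide table file must have 'peptide' and 'protein_id' columns")
  sample_cols <- setdiff(names(df), meta_cols)
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  peptide_table(m, df$peptide, df$protein_id,
                if ("flank_context" %in% names(df)) df$flank_context
                else NA_character_,
                scale = scale)
}

#' Write / read a sample sheet (sample id and binary class) as TSV
#'
#' @param labels a [group_labels] vector.
#' @param file path to a two-column TSV (`sample_id`, `class`).
#' @export
write_sample_sheet <- function(labels, file) {
  df <- data.frame(sample_id = names(labels),
                   class = as.integer(unclass(labels)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  group_labels(df$class, df$sample_id)
}
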