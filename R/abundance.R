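#' Protein-by-sample abundance matrix
#'
#' The central container of the secretome track: a numeric matrix of protein
#' abundances (rows = proteins, columns = samples) with a condition label per
#' sample and, optionally, the number of unique peptides supporting each
#' protein identification. Missing values are `NA`, never zero: a protein not
#' detected in a sample carries no abundance, and the distinction drives the
#' qualitative (Venn) track.
#'
#' @param values Numeric matrix with unique rownames (protein accessions) and
#'   unique colnames (sample ids). Values must be non-negative or `NA`.
#' @param conditions Character vector of condition labels, one per column
#'   (e.g. `"CTR"`, `"FSH"`, `"hCG"`, `"FSH_hCG"`).
#' @param unique_peptides Optional integer vector, one per protein, giving the
#'   number of unique peptides supporting the identification.
#' @param protein_names Optional character vector of human-readable protein
#'   names parallel to the rows.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `conditions` (named by sample), `unique_peptides` and
#'   `protein_names`.
#' @export
abundance_matrix <- function(values, conditions, unique_peptides = NULL,
                             protein_names = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (protein ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique colnames (sample ids)")
  if (any(!is.na(values) & (!is.finite(values) | values < 0)))
    stop("abundances must be finite and non-negative where present")
  if (length(conditions) != ncol(values))
    stop("`conditions` must have one label per sample")
  conditions <- stats::setNames(as.character(conditions), colnames(values))
  if (!is.null(unique_peptides)) {
    if (length(unique_peptides) != nrow(values))
      stop("`unique_peptides` must have one entry per protein")
    unique_peptides <- stats::setNames(as.integer(unique_peptides),
                                       rownames(values))
  }
  if (!is.null(protein_names)) {
    if (length(protein_names) != nrow(values))
      stop("`protein_names` must have one entry per protein")
    protein_names <- stats::setNames(as.character(protein_names),
                                     rownames(values))
  }
  structure(list(values = values, conditions = conditions,
                 unique_peptides = unique_peptides,
                 protein_names = protein_names),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(sprintf("%s (n=%d)", names(table(x$conditions)),
                                   as.integer(table(x$conditions))),
                           collapse = ", "), "\n")
  cat(sprintf("missing values: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# columns of the value matrix belonging to one condition
condition_columns <- function(x, condition) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (!condition %in% x$conditions)
    stop(sprintf("unknown condition '%s'; available: %s", condition,
                 paste(unique(x$conditions), collapse = ", ")))
  which(x$conditions == condition)
}

#' Write / read an abundance matrix as TSV
#'
#' Plain tab-separated serialization: one row per protein with columns
#' `protein_id`, optional `protein_name`, optional `unique_peptides`, then one
#' column per sample. Missing abundances are written as empty fields.
#' Condition labels are recovered from the sample column names, which must
#' follow the `<condition>_<replicate>` convention (e.g. `FSH_hCG_2`), unless
#' `conditions` is supplied explicitly on read.
#'
#' @param x An `abundance_matrix`.
#' @param path File path.
#' @return `write_abundance_tsv` returns `path` invisibly;
#'   `read_abundance_tsv` returns an `abundance_matrix`.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(protein_id = rownames(x$values), stringsAsFactors = FALSE)
  if (!is.null(x$protein_names)) df$protein_name <- unname(x$protein_names)
  if (!is.null(x$unique_peptides)) df$unique_peptides <- unname(x$unique_peptides)
  df <- cbind(df, as.data.frame(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @param conditions Optional character vector of condition labels per sample
#'   column; by default they are parsed from the column names.
#' @export
read_abundance_tsv <- function(path, conditions = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  meta <- intersect(c("protein_id", "protein_name", "unique_peptides"),
                    colnames(df))
  sample_cols <- setdiff(colnames(df), meta)
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$protein_id
  if (is.null(conditions))
    conditions <- sub("_[0-9]+$", "", sample_cols)
  abundance_matrix(values, conditions,
                   unique_peptides = if ("unique_peptides" %in% meta)
                     df$unique_peptides,
                   protein_names = if ("protein_name" %in% meta)
                     df$protein_name)
}

#' Bundled reference differential tables
#'
#' Log2 fold-change tables (treatment vs untreated control) from a published
#' KGN granulosa-cell gonadotropin-stimulation secretome experiment, bundled
#' as plain-text fixtures. Each table lists the differentially secreted
#' proteins for one contrast, with the printed log2 fold change.
#'
#' @param contrast One of `"fsh"`, `"hcg"`, `"fsh_hcg"`.
#' @return A data.frame with columns `protein` and `log2fc`.
#' @export
reference_differential_table <- function(contrast = c("fsh", "hcg", "fsh_hcg")) {
  contrast <- match.arg(contrast)
  file <- c(fsh = "table1a_fsh_log2fc.tsv",
            hcg = "table1b_hcg_log2fc.tsv",
            fsh_hcg = "table1c_fsh_hcg_log2fc.tsv")[[contrast]]
  path <- system.file("extdata", file, package = "secretofft", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  df[, c("protein", "log2fc")]
}
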