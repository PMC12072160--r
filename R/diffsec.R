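#' Filter proteins by unique-peptide support
#'
#' Retains proteins identified by at least `k` unique peptides, the standard
#' high-confidence identification filter applied before any secretome
#' analysis. Row order is preserved.
#'
#' @param x An [abundance_matrix()] with `unique_peptides` set.
#' @param k Minimum number of unique peptides (default 2).
#' @return The filtered `abundance_matrix`.
#' @export
filter_min_unique_peptides <- function(x, k = 2) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (k < 1) stop("`k` must be >= 1")
  if (is.null(x$unique_peptides))
    stop("`x` carries no unique-peptide counts")
  keep <- x$unique_peptides >= k
  abundance_matrix(x$values[keep, , drop = FALSE], x$conditions,
                   unique_peptides = x$unique_peptides[keep],
                   protein_names = x$protein_names[keep])
}

#' Proteins identified in a condition
#'
#' A protein counts as identified in a condition when it has at least one
#' observed (non-missing) abundance in at least one replicate of that
#' condition — the most permissive reading, matching the qualitative intent
#' of identification lists.
#'
#' @param x An [abundance_matrix()].
#' @param condition Condition label.
#' @return Character vector of protein ids.
#' @export
identified_set <- function(x, condition) {
  cols <- condition_columns(x, condition)
  rownames(x$values)[rowSums(!is.na(x$values[, cols, drop = FALSE])) > 0]
}

#' Venn partition of two identification lists
#'
#' Splits the union of a treatment and a control identification list into
#' the proteins common to both, those exclusive to the treatment, and those
#' exclusive to the control.
#'
#' @param a Treatment identification set (character).
#' @param b Control identification set (character).
#' @return A list of class `venn_partition` with elements `common`,
#'   `treatment_only`, `control_only`.
#' @export
venn_partition <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  structure(list(common = intersect(a, b),
                 treatment_only = setdiff(a, b),
                 control_only = setdiff(b, a)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: %d common, %d treatment-only, %d control-only\n",
              length(x$common), length(x$treatment_only),
              length(x$control_only)))
  invisible(x)
}

#' Quantile normalization
#'
#' Forces every sample to share the same abundance distribution: the
#' reference distribution is the mean of the per-sample quantile functions,
#' and each observed value is mapped to the reference quantile of its
#' within-sample rank (tied values receive the average rank, hence the
#' midpoint of the tied reference quantiles). Missing values stay missing
#' and do not take part in the ranking, so condition-exclusive proteins are
#' untouched. On complete matrices this coincides with the classical
#' sorted-row-means construction.
#'
#' @param x An [abundance_matrix()] or a numeric matrix with at least two
#'   columns.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "abundance_matrix")) {
    out <- x
    out$values <- quantile_normalize(x$values)
    return(out)
  }
  m <- x
  if (!is.matrix(m) || ncol(m) < 2)
    stop("need a matrix with at least 2 samples")
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0))
    stop("all-missing column(s): ",
         paste(colnames(m)[n_obs == 0], collapse = ", "))
  n <- nrow(m)
  grid <- (seq_len(n) - 0.5) / n
  qcols <- vapply(seq_len(ncol(m)), function(j) {
    s <- sort(m[, j])   # drops NA
    stats::approx((seq_along(s) - 0.5) / length(s), s, xout = grid,
                  rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(qcols)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- !is.na(m[, j])
    r <- rank(m[obs, j], ties.method = "average")
    p <- (r - 0.5) / sum(obs)
    out[obs, j] <- stats::approx(grid, ref, xout = p, rule = 2)$y
  }
  out
}

#' Log2 fold changes between two conditions
#'
#' Per protein, the log2 ratio of the mean abundance over treatment
#' replicates to the mean over control replicates (means over observed
#' replicates; intended to be applied after [quantile_normalize()]).
#' Proteins with no observed value in either condition are excluded — they
#' belong to the qualitative Venn track, not the quantitative comparison.
#' Proteins with a non-positive mean are excluded with a warning.
#'
#' @param x An [abundance_matrix()].
#' @param treatment,control Condition labels.
#' @return A data.frame with columns `protein` and `log2fc`.
#' @export
log2_fold_change <- function(x, treatment, control) {
  tc <- condition_columns(x, treatment)
  cc <- condition_columns(x, control)
  tm <- rowMeans(x$values[, tc, drop = FALSE], na.rm = TRUE)
  cm <- rowMeans(x$values[, cc, drop = FALSE], na.rm = TRUE)
  quantified <- is.finite(tm) & is.finite(cm)   # NaN when all replicates NA
  bad <- quantified & (tm <= 0 | cm <= 0)
  if (any(bad))
    warning(sprintf("%d protein(s) with non-positive condition mean excluded",
                    sum(bad)))
  keep <- quantified & !bad
  data.frame(protein = rownames(x$values)[keep],
             log2fc = log2(tm[keep] / cm[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify differential records by a log2 fold-change threshold
#'
#' Applies the strict threshold rule: `UP` when `log2fc > threshold`, `DOWN`
#' when `log2fc < -threshold`, otherwise `NS` (not significant). A value
#' exactly at the threshold is `NS`.
#'
#' @param records Data.frame with a `log2fc` column (as from
#'   [log2_fold_change()]).
#' @param threshold Positive threshold on the log2 fold change (default 1.5).
#' @return The input with an added `call` column (`UP`/`DOWN`/`NS`).
#' @export
classify_differential <- function(records, threshold = 1.5) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  if (!"log2fc" %in% colnames(records)) stop("records need a `log2fc` column")
  if (any(!is.finite(records$log2fc))) stop("log2fc must be finite")
  records$call <- ifelse(records$log2fc > threshold, "UP",
                         ifelse(records$log2fc < -threshold, "DOWN", "NS"))
  records
}

#' Row-wise Z-score autoscaling of log abundances
#'
#' The clustergram transform: each protein's abundances are log-transformed,
#' then centered and scaled to unit standard deviation across samples
#' (`z = (log x - mean) / sd`). Only proteins quantified in all samples are
#' eligible; rows with zero variance are dropped with a warning. The log
#' base is immaterial — autoscaling removes it — so the natural log is used.
#'
#' @param x An [abundance_matrix()] or numeric matrix; rows with any missing
#'   value are dropped (with a message when any are).
#' @return Numeric matrix of Z-scores.
#' @export
zscore_autoscale <- function(x) {
  m <- if (inherits(x, "abundance_matrix")) x$values else x
  complete <- rowSums(is.na(m)) == 0
  if (!all(complete)) {
    message(sprintf("dropping %d protein(s) not quantified in all samples",
                    sum(!complete)))
    m <- m[complete, , drop = FALSE]
  }
  if (any(m <= 0))
    stop("non-positive abundance under log for protein(s): ",
         paste(utils::head(rownames(m)[apply(m <= 0, 1, any)], 5),
               collapse = ", "))
  l <- log(m)
  sds <- apply(l, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance row(s)", sum(sds == 0)))
    l <- l[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (l - rowMeans(l)) / sds
}

#' Hierarchically clustered Z-score heatmap structure
#'
#' Agglomerative clustering of the Z-scored matrix along both axes, as drawn
#' in a clustergram. Distances are euclidean or correlation-based
#' (`1 - Pearson r`); linkage is average (default), complete, or Ward.
#'
#' @param zscores Numeric matrix (as from [zscore_autoscale()]), no
#'   missing/non-finite entries, at least 2 rows and 2 columns.
#' @param linkage One of `"average"`, `"ward"`, `"complete"`.
#' @param metric One of `"euclidean"`, `"correlation"`.
#' @return A list of class `clustergram`: `zscores`, `row_tree`, `col_tree`
#'   (`hclust` objects), `row_order`, `col_order`.
#' @export
clustergram <- function(zscores, linkage = c("average", "ward", "complete"),
                        metric = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (!is.matrix(zscores) || nrow(zscores) < 2 || ncol(zscores) < 2)
    stop("`zscores` must be a matrix with >= 2 rows and columns")
  if (any(!is.finite(zscores))) stop("`zscores` contains non-finite values")
  method <- c(average = "average", ward = "ward.D2",
              complete = "complete")[[linkage]]
  dfun <- function(m) {
    if (metric == "euclidean") stats::dist(m)
    else stats::as.dist(1 - stats::cor(t(m)))
  }
  row_tree <- stats::hclust(dfun(zscores), method = method)
  col_tree <- stats::hclust(dfun(t(zscores)), method = method)
  structure(list(zscores = zscores, row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 linkage = linkage, metric = metric),
            class = "clustergram")
}

#' Export a clustergram
#'
#' Writes the Z-score matrix as TSV and the two dendrograms as Newick trees.
#'
#' @param cg A `clustergram`.
#' @param prefix Output path prefix; writes `<prefix>_zscores.tsv`,
#'   `<prefix>_rows.nwk`, `<prefix>_cols.nwk`.
#' @export
write_clustergram <- function(cg, prefix) {
  stopifnot(inherits(cg, "clustergram"))
  utils::write.table(
    data.frame(protein = rownames(cg$zscores), cg$zscores,
               check.names = FALSE),
    paste0(prefix, "_zscores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(ape::as.phylo(cg$row_tree), paste0(prefix, "_rows.nwk"))
  ape::write.tree(ape::as.phylo(cg$col_tree), paste0(prefix, "_cols.nwk"))
  invisible(prefix)
}
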