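#' Parameters for the synthetic secretome generator
#'
#' Describes a label-free secretome experiment at the peptide level: a set of
#' proteins with log-normal baseline abundances, observed in analytical
#' triplicate per condition, with condition-specific multiplicative effects
#' (fold changes), multiplicative replicate noise of a given coefficient of
#' variation, and whole-condition dropout. Dropout removes a protein from
#' every replicate of a condition, producing the exclusive/common
#' identification classes that the Venn track partitions.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param peptides_per_protein Integer range `c(min, max)` of peptides per
#'   protein, drawn uniformly.
#' @param base_meanlog,base_sdlog Location and scale of the log-normal
#'   baseline protein abundance (arbitrary precursor-area units).
#' @param effects Named list mapping protein id to a named numeric vector of
#'   multiplicative effects per condition (conditions not listed default to
#'   1; effects must be > 0). Protein ids are `P0001`, `P0002`, ...
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate noise (log-normal, mean one).
#' @param dropout_rate Probability that a protein is undetected in an entire
#'   condition (all peptides, all replicates missing); in `[0, 1]`.
#' @param conditions Condition labels; the first is treated as the control by
#'   downstream helpers but nothing here depends on it.
#' @param n_replicates Replicates per condition.
#' @param peptide_sdlog Scale of the per-peptide log-normal ionization
#'   efficiency factor (spreads peptide areas within a protein).
#' @param seed Integer seed; the generator draws from its own RNG stream.
#' @return A validated list of class `secretome_sim_params`.
#' @export
secretome_sim_params <- function(n_proteins = 500,
                                 peptides_per_protein = c(2, 8),
                                 base_meanlog = log(1e6),
                                 base_sdlog = 1,
                                 effects = NULL,
                                 replicate_cv = 0.2,
                                 dropout_rate = 0.1,
                                 conditions = c("CTR", "FSH", "hCG", "FSH_hCG"),
                                 n_replicates = 3,
                                 peptide_sdlog = 0.5,
                                 seed = 1L) {
  if (n_proteins < 1) stop("`n_proteins` must be >= 1")
  if (length(peptides_per_protein) != 2 ||
      peptides_per_protein[1] < 1 ||
      peptides_per_protein[1] > peptides_per_protein[2])
    stop("`peptides_per_protein` must be an increasing range of positive ints")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("`dropout_rate` must be in [0, 1]")
  if (replicate_cv < 0) stop("`replicate_cv` must be >= 0")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (anyDuplicated(conditions)) stop("`conditions` must be unique")
  if (!is.null(effects)) {
    if (is.null(names(effects))) stop("`effects` must be a named list")
    for (e in effects) {
      if (is.null(names(e)) || !all(names(e) %in% conditions))
        stop("effect conditions must be named and among `conditions`")
      if (any(e <= 0)) stop("effects must be > 0")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 effects = effects, replicate_cv = replicate_cv,
                 dropout_rate = dropout_rate, conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 peptide_sdlog = peptide_sdlog, seed = as.integer(seed)),
            class = "secretome_sim_params")
}

#' Simulate a peptide-level abundance table
#'
#' Draws a peptide precursor-area table under the model of
#' [secretome_sim_params()]. Per replicate, a peptide area is
#' `baseline(protein) * efficiency(peptide) * effect(protein, condition) *
#' noise`, with log-normal mean-one noise whose coefficient of variation is
#' `replicate_cv`, so the expected log2 ratio of a protein's condition mean
#' to the control mean equals `log2(effect)`. Proteins hit by dropout in a
#' condition are `NA` in all peptides and replicates of that condition.
#'
#' @param params A `secretome_sim_params` object.
#' @return A data.frame of class `peptide_table` with columns `protein_id`,
#'   `peptide_id` and one area column per sample (named
#'   `<condition>_<replicate>`). Attributes: `conditions` (sample ->
#'   condition), `dropout` (protein x condition logical matrix, the
#'   generator's bookkeeping) and `params`.
#' @export
simulate_peptide_table <- function(params) {
  stopifnot(inherits(params, "secretome_sim_params"))
  withr::with_seed(params$seed, {
    p <- params
    prot_ids <- sprintf("P%04d", seq_len(p$n_proteins))
    n_pep <- sample(seq(p$peptides_per_protein[1], p$peptides_per_protein[2]),
                    p$n_proteins, replace = TRUE)
    baseline <- stats::rlnorm(p$n_proteins, p$base_meanlog, p$base_sdlog)

    effect <- matrix(1, p$n_proteins, length(p$conditions),
                     dimnames = list(prot_ids, p$conditions))
    for (id in names(p$effects))
      effect[id, names(p$effects[[id]])] <- p$effects[[id]]

    dropout <- matrix(stats::runif(p$n_proteins * length(p$conditions)) <
                        p$dropout_rate,
                      p$n_proteins, length(p$conditions),
                      dimnames = list(prot_ids, p$conditions))

    samples <- as.vector(t(outer(p$conditions, seq_len(p$n_replicates),
                                 paste, sep = "_")))
    sample_cond <- rep(p$conditions, each = p$n_replicates)

    protein_of_pep <- rep(seq_len(p$n_proteins), n_pep)
    pep_ids <- unlist(lapply(seq_len(p$n_proteins), function(i)
      sprintf("%s_pep%02d", prot_ids[i], seq_len(n_pep[i]))))
    # mean-one log-normal noise: sdlog chosen so that CV == replicate_cv
    noise_sdlog <- sqrt(log(1 + p$replicate_cv^2))
    efficiency <- stats::rlnorm(length(pep_ids), 0, p$peptide_sdlog)

    areas <- matrix(NA_real_, length(pep_ids), length(samples),
                    dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      cond <- sample_cond[j]
      mu <- baseline[protein_of_pep] * efficiency *
        effect[cbind(protein_of_pep, match(cond, p$conditions))]
      noise <- stats::rlnorm(length(pep_ids), -noise_sdlog^2 / 2, noise_sdlog)
      v <- mu * noise
      v[dropout[protein_of_pep, cond]] <- NA_real_
      areas[, j] <- v
    }

    out <- cbind(data.frame(protein_id = prot_ids[protein_of_pep],
                            peptide_id = pep_ids,
                            stringsAsFactors = FALSE),
                 as.data.frame(areas))
    attr(out, "conditions") <- stats::setNames(sample_cond, samples)
    attr(out, "dropout") <- dropout
    attr(out, "params") <- params
    class(out) <- c("peptide_table", "data.frame")
    out
  })
}

#' Top-3 label-free protein quantification
#'
#' Aggregates a peptide-level table to protein abundances as the mean of the
#' three largest non-missing peptide areas per protein and sample ("top-3
#' average precursor area"). Proteins with fewer than three observed peptides
#' in a sample are averaged over those available; a protein with no observed
#' peptide in a sample is missing (`NA`) there. The number of peptides
#' assigned to each protein is recorded as its unique-peptide count.
#'
#' @param table A `peptide_table` (or a data.frame with `protein_id`,
#'   `peptide_id` and sample columns).
#' @param conditions Optional condition labels per sample column; defaults to
#'   the table's `conditions` attribute, else parsed from column names.
#' @return An [abundance_matrix()].
#' @export
top3_quantify <- function(table, conditions = NULL) {
  if (nrow(table) == 0) stop("`table` must be nonempty")
  if (!all(c("protein_id", "peptide_id") %in% colnames(table)))
    stop("`table` must have protein_id and peptide_id columns")
  sample_cols <- setdiff(colnames(table), c("protein_id", "peptide_id"))
  if (is.null(conditions)) {
    conds <- attr(table, "conditions")
    conditions <- if (!is.null(conds)) unname(conds[sample_cols]) else
      sub("_[0-9]+$", "", sample_cols)
  }
  prot <- unique(table$protein_id)
  values <- matrix(NA_real_, length(prot), length(sample_cols),
                   dimnames = list(prot, sample_cols))
  idx <- split(seq_len(nrow(table)), table$protein_id)
  for (pid in prot) {
    sub <- as.matrix(table[idx[[pid]], sample_cols, drop = FALSE])
    values[pid, ] <- apply(sub, 2, function(a) {
      a <- a[!is.na(a)]
      if (length(a) == 0) return(NA_real_)
      mean(sort(a, decreasing = TRUE)[seq_len(min(3, length(a)))])
    })
  }
  abundance_matrix(values, conditions,
                   unique_peptides = lengths(idx)[prot])
}

#' Write / read a peptide table as TSV
#'
#' Serialization with header `protein_id`, `peptide_id`, then one column per
#' sample; missing areas are empty fields.
#'
#' @param table A `peptide_table`.
#' @param path File path.
#' @export
write_peptide_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_peptide_tsv
#' @export
read_peptide_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  sample_cols <- setdiff(colnames(df), c("protein_id", "peptide_id"))
  attr(df, "conditions") <- stats::setNames(sub("_[0-9]+$", "", sample_cols),
                                            sample_cols)
  class(df) <- c("peptide_table", "data.frame")
  df
}
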