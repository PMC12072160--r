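# Exhaustive hypergeometric upper-tail oracle: enumerate every draw of n
# items from a background of N (items 1..K are the pathway members) and
# count draws whose overlap with the pathway is at least x.
enum_hyper_p <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= x)
}

# pathway_db with a single pathway of the first K of N background ids
one_pathway_db <- function(N, K) {
  ids <- sprintf("p%02d", seq_len(N))
  pathway_db(list(PW1 = list(name = "toy", members = ids[seq_len(K)])),
             background = ids)
}

# smallest axial (180-degree periodic) distance between two orientations
axial_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# small complete abundance matrix with labelled conditions
toy_abundance <- function(values, conditions, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste(conditions, ave(seq_along(conditions),
                                              conditions, FUN = seq_along),
                              sep = "_")
  abundance_matrix(values, conditions, ...)
}
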