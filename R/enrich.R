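#' Read a GMT pathway-set file
#'
#' Parses the standard tab-separated gene/protein set format: one set per
#' line, `id<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer
#' than three fields or an empty member list are rejected with the offending
#' line number. The background universe defaults to the union of all set
#' members; a user-supplied universe (e.g. all identified secretome
#' proteins) is recommended for over-representation analysis, in which case
#' members outside it are dropped with a warning.
#'
#' @param path GMT file path.
#' @param background Optional explicit background universe (character).
#' @return A list of class `pathway_db`: `pathways` (named list with `name`
#'   and `members`) and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  pathways <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d: expected id, description and at least one member", i))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("malformed GMT line %d: empty member list", i))
    if (fields[1] %in% names(pathways))
      stop(sprintf("duplicate pathway id '%s' at line %d", fields[1], i))
    pathways[[fields[1]]] <- list(name = fields[2], members = members)
  }
  pathway_db(pathways, background)
}

#' Construct a pathway database
#'
#' @param pathways Named list, each element a list with `name` (string) and
#'   `members` (character vector).
#' @param background Optional background universe; defaults to the union of
#'   all members. Members outside a supplied background are dropped with a
#'   warning.
#' @return A `pathway_db` object.
#' @export
pathway_db <- function(pathways, background = NULL) {
  if (length(pathways) == 0) stop("no pathways")
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    stop("pathway ids must be unique and named")
  all_members <- unique(unlist(lapply(pathways, `[[`, "members")))
  if (is.null(background)) {
    background <- all_members
  } else {
    background <- unique(as.character(background))
    outside <- setdiff(all_members, background)
    if (length(outside) > 0) {
      warning(sprintf("%d pathway member(s) outside the background dropped",
                      length(outside)))
      pathways <- lapply(pathways, function(p) {
        p$members <- intersect(p$members, background); p
      })
      pathways <- Filter(function(p) length(p$members) > 0, pathways)
      if (length(pathways) == 0) stop("no pathway retains any member")
    }
  }
  structure(list(pathways = pathways, background = background),
            class = "pathway_db")
}

#' Write a pathway database as GMT
#'
#' @param db A `pathway_db`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$pathways), function(id) {
    p <- db$pathways[[id]]
    paste(c(id, p$name, p$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway, tests whether the query list overlaps the pathway's
#' member set more than expected when drawing `|query|` proteins from the
#' background: the upper-tail hypergeometric probability `P(X >= found)`,
#' the documented over-representation model behind the "entities found /
#' entities total / entities p-value / entities FDR" columns of pathway
#' reports. P-values are corrected across pathways with Benjamini-Hochberg
#' by default.
#'
#' @param query Character vector of protein ids; members outside the
#'   background are dropped with a warning; an empty query is an error.
#' @param db A `pathway_db`.
#' @param fdr_method Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A data.frame sorted by ascending p-value with columns
#'   `pathway_id`, `pathway_name`, `found`, `total`, `pvalue`, `fdr`.
#' @export
hypergeom_enrich <- function(query, db, fdr_method = "BH") {
  stopifnot(inherits(db, "pathway_db"))
  query <- unique(as.character(query))
  outside <- setdiff(query, db$background)
  if (length(outside) > 0) {
    warning(sprintf("%d query protein(s) outside the background dropped",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("empty query")
  N <- length(db$background)
  n <- length(query)
  rows <- lapply(names(db$pathways), function(id) {
    p <- db$pathways[[id]]
    K <- length(p$members)
    x <- length(intersect(query, p$members))
    data.frame(pathway_id = id, pathway_name = p$name, found = x, total = K,
               pvalue = stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = fdr_method)
  out <- out[order(out$pvalue), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' smallest p is `min over j >= i of p_(j) * m / j`, capped at 1, returned
#' in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Write an enrichment table as TSV
#'
#' @param rows Data.frame from [hypergeom_enrich()].
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
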