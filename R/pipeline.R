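#' Run the full secretome analysis pipeline
#'
#' End-to-end quantitative and qualitative secretome analysis: unique-peptide
#' filtering, per-contrast Venn partitioning of identification lists,
#' quantile normalization, log2 fold changes with threshold classification,
#' Z-score clustergram, and (optionally) hypergeometric pathway
#' over-representation of the UP and DOWN lists. All outputs are plain text
#' (JSON/TSV/Newick) under `out_dir` and embed an md5 hash of the run
#' configuration, so identical hashes imply identical scientific content.
#'
#' @param input One of: a [secretome_sim_params()] object (simulated first),
#'   a `peptide_table` (quantified with [top3_quantify()]), an
#'   [abundance_matrix()], or a path to an abundance TSV.
#' @param out_dir Output directory (created if needed).
#' @param control Control condition label (default `"CTR"`).
#' @param treatments Treatment labels; default all non-control conditions.
#' @param threshold Log2 fold-change threshold (default 1.5).
#' @param min_unique_peptides Unique-peptide filter (default 2; `NULL`
#'   skips when no counts are available).
#' @param gmt Optional path to a GMT file, or a `pathway_db`, for
#'   enrichment of the UP/DOWN lists.
#' @param enrich_background Optional explicit background for enrichment;
#'   default: all quantified proteins if they cover the GMT, else the GMT
#'   union.
#' @param linkage,metric Clustergram options.
#' @return Invisibly, a list with the intermediate results (`abundance`,
#'   `venn`, `differential`, `clustergram`, `enrichment`, `paths`).
#' @export
run_secretome_pipeline <- function(input, out_dir, control = "CTR",
                                   treatments = NULL, threshold = 1.5,
                                   min_unique_peptides = 2, gmt = NULL,
                                   enrich_background = NULL,
                                   linkage = "average", metric = "euclidean") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(input, "secretome_sim_params"))
    input <- simulate_peptide_table(input)
  if (inherits(input, "peptide_table")) input <- top3_quantify(input)
  if (is.character(input)) input <- read_abundance_tsv(input)
  stopifnot(inherits(input, "abundance_matrix"))

  cfg <- list(control = control, treatments = treatments,
              threshold = threshold,
              min_unique_peptides = min_unique_peptides,
              linkage = linkage, metric = metric)
  hash <- config_hash(cfg)
  if (is.null(treatments))
    treatments <- setdiff(unique(input$conditions), control)

  x <- input
  if (!is.null(min_unique_peptides) && !is.null(x$unique_peptides))
    x <- filter_min_unique_peptides(x, min_unique_peptides)

  paths <- list()
  ctrl_set <- identified_set(x, control)
  venns <- lapply(treatments, function(tr)
    venn_partition(identified_set(x, tr), ctrl_set))
  names(venns) <- treatments
  paths$venn <- file.path(out_dir, "venn.json")
  jsonlite::write_json(c(list(config_md5 = hash),
                         lapply(venns, unclass)),
                       paths$venn, auto_unbox = TRUE, pretty = TRUE)

  xn <- quantile_normalize(x)
  diffs <- lapply(treatments, function(tr) {
    rec <- classify_differential(log2_fold_change(xn, tr, control),
                                 threshold = threshold)
    path <- file.path(out_dir, sprintf("differential_%s_vs_%s.tsv",
                                       tr, control))
    write_tsv_hashed(rec, path, hash)
    rec
  })
  names(diffs) <- treatments
  paths$differential <- file.path(out_dir, sprintf("differential_%s_vs_%s.tsv",
                                                   treatments, control))

  cg <- NULL
  # after quantile normalization, proteins with a constant rank across
  # samples have zero variance; dropping them here is routine
  z <- suppressWarnings(suppressMessages(zscore_autoscale(xn)))
  if (nrow(z) >= 2 && ncol(z) >= 2) {
    cg <- clustergram(z, linkage = linkage, metric = metric)
    prefix <- file.path(out_dir, "clustergram")
    write_clustergram(cg, prefix)
    paths$clustergram <- paste0(prefix, c("_zscores.tsv", "_rows.nwk",
                                          "_cols.nwk"))
  }

  enrichment <- NULL
  if (!is.null(gmt)) {
    db <- if (inherits(gmt, "pathway_db")) gmt else read_gmt(gmt)
    if (!is.null(enrich_background))
      db <- pathway_db(db$pathways, enrich_background)
    enrichment <- list()
    for (tr in treatments) {
      for (dir_call in c("UP", "DOWN")) {
        q <- diffs[[tr]]$protein[diffs[[tr]]$call == dir_call]
        q <- intersect(q, db$background)
        if (length(q) == 0) next
        rows <- hypergeom_enrich(q, db)
        key <- sprintf("%s_%s", tr, tolower(dir_call))
        path <- file.path(out_dir, sprintf("enrichment_%s.tsv", key))
        write_tsv_hashed(rows, path, hash)
        enrichment[[key]] <- rows
        paths$enrichment <- c(paths$enrichment, path)
      }
    }
  }

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(
    list(config = cfg, config_md5 = hash,
         package_version = as.character(utils::packageVersion("secretofft")),
         n_proteins = nrow(x$values), n_samples = ncol(x$values),
         contrasts = sprintf("%s_vs_%s", treatments, control)),
    log_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$run_log <- log_path

  invisible(list(abundance = xn, venn = venns, differential = diffs,
                 clustergram = cg, enrichment = enrichment, paths = paths))
}

#' Run the fiber-image analysis pipeline
#'
#' Simulates (or loads) one or more filament images per condition, measures
#' per-ROI spectral metrics, and compares the conditions with a one-way
#' ANOVA plus Bonferroni post hoc on the chosen metric. With a single
#' condition the comparison is skipped with a message, and the metrics are
#' still written.
#'
#' @param groups Named list, one element per condition. Each element is a
#'   list of [fiber_sim_params()] (simulated), a character vector of image
#'   paths (read with [read_fiber_image()]), or a list of image matrices.
#' @param out_dir Output directory.
#' @param n_rois ROIs per image.
#' @param config An [fft_config()].
#' @param strategy ROI selection strategy (see [select_rois()]).
#' @param value Metric compared across conditions (default `"amplitude"`).
#' @param seed Seed forwarded to random ROI selection and bootstrap CIs.
#' @return Invisibly, a list with `metrics` (data.frame), `comparison`
#'   (a `group_comparison` or `NULL`) and `paths`.
#' @export
run_fiber_pipeline <- function(groups, out_dir, n_rois = 5,
                               config = fft_config(), strategy = "grid",
                               value = "amplitude", seed = 1L) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("`groups` must be a uniquely named list of conditions")
  if (strategy == "mask")
    stop("the pipeline has no per-image masks; call image_metrics() directly")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(n_rois = n_rois, roi_size = config$roi_size,
              band = config$band, n_bins = config$n_bins,
              window = config$window, weight = config$weight,
              strategy = strategy, value = value,
              seed = seed)
  hash <- config_hash(cfg)

  metrics <- list()
  for (cond in names(groups)) {
    items <- groups[[cond]]
    if (inherits(items, "fiber_sim_params")) items <- list(items)
    if (is.character(items)) items <- as.list(items)
    for (i in seq_along(items)) {
      it <- items[[i]]
      img <- if (inherits(it, "fiber_sim_params")) simulate_fiber_image(it)
      else if (is.character(it)) read_fiber_image(it)
      else it
      m <- image_metrics(img, config = config, n = n_rois,
                         strategy = strategy, seed = seed + i)
      m <- cbind(condition = cond,
                 image = if (is.character(it)) basename(it)
                 else sprintf("%s_img%02d", cond, i),
                 m)
      metrics[[length(metrics) + 1]] <- m
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics_path <- file.path(out_dir, "metrics.tsv")
  write_tsv_hashed(metrics, metrics_path, hash)

  comparison <- NULL
  if (length(groups) >= 2) {
    comparison <- compare_groups(metrics, value = value, group = "condition",
                                 seed = seed)
    jsonlite::write_json(
      list(config_md5 = hash, value = value,
           anova = comparison$anova[c("F", "p", "df")],
           pairwise = comparison$pairwise,
           summaries = comparison$summaries),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  } else {
    message("single condition: group comparison skipped")
  }
  invisible(list(metrics = metrics, comparison = comparison,
                 paths = list(metrics = metrics_path,
                              comparison = if (!is.null(comparison))
                                file.path(out_dir, "comparison.json"))))
}

# md5 of the JSON-serialized configuration
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# TSV with a leading comment line carrying the configuration hash
write_tsv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5 %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
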