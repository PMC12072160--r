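test_that("unique-peptide filter applies the threshold and keeps order", {
  m <- toy_abundance(matrix(1:12, 3, 4), c("CTR", "CTR", "FSH", "FSH"),
                     unique_peptides = c(1, 2, 5))
  f <- filter_min_unique_peptides(m, 2)
  expect_identical(rownames(f$values), c("P02", "P03"))
  expect_identical(filter_min_unique_peptides(m, 1)$values, m$values)
  # brute-force oracle on a random table
  withr::with_seed(1, up <- sample(0:6, 40, replace = TRUE))
  m2 <- toy_abundance(matrix(runif(80), 40, 2), c("CTR", "FSH"),
                      unique_peptides = up)
  expect_identical(rownames(filter_min_unique_peptides(m2, 2)$values),
                   sprintf("P%02d", which(up >= 2)))
})

test_that("identified sets use any observed replicate; unknown condition errors", {
  v <- matrix(c(1, NA, NA, NA, NA, NA, 2, 3, 4, 5, 6, 7), 2, 6, byrow = TRUE,
              dimnames = list(c("A", "B"), NULL))
  colnames(v) <- c("CTR_1", "CTR_2", "CTR_3", "FSH_1", "FSH_2", "FSH_3")
  m <- abundance_matrix(v, rep(c("CTR", "FSH"), each = 3))
  expect_identical(identified_set(m, "CTR"), c("A", "B"))  # 1 of 3 counts
  expect_identical(identified_set(m, "FSH"), "B")          # all-NA excluded
  expect_error(identified_set(m, "LH"), "unknown condition")
})

test_that("venn partition is exact and conserves the union", {
  v <- venn_partition(c("x", "y", "z"), c("y", "z", "w"))
  expect_setequal(v$common, c("y", "z"))
  expect_identical(v$treatment_only, "x")
  expect_identical(v$control_only, "w")
  same <- venn_partition(letters[1:4], letters[1:4])
  expect_length(same$treatment_only, 0)
  expect_length(same$control_only, 0)
  # conservation property over random sets
  withr::with_seed(3, for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    p <- venn_partition(a, b)
    expect_length(intersect(p$common, p$treatment_only), 0)
    expect_length(intersect(p$common, p$control_only), 0)
    expect_equal(length(p$common) + length(p$treatment_only) +
                   length(p$control_only), length(union(a, b)))
  })
})

test_that("quantile normalization matches hand values, is idempotent and limma", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- c("a", "b", "c")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)            # fixed point
  withr::with_seed(8, r <- matrix(rlnorm(200 * 4), 200, 4,
                                  dimnames = list(NULL, letters[1:4])))
  q1 <- quantile_normalize(r)
  sorted <- apply(q1, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)        # identical columns
  expect_lt(max(abs(quantile_normalize(q1) - q1)), 1e-10) # idempotent
  skip_if_not_installed("limma")
  expect_equal(q1, limma::normalizeQuantiles(r), tolerance = 1e-10)
})

test_that("quantile normalization handles missing values and rejects empty columns", {
  withr::with_seed(9, {
    r <- matrix(rlnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
    r[sample(200, 30)] <- NA
  })
  qn <- quantile_normalize(r)
  expect_identical(is.na(qn), is.na(r))                   # missing preserved
  # within-column order preserved among observed values
  for (j in 1:4) {
    o <- !is.na(r[, j])
    expect_identical(order(r[o, j]), order(qn[o, j]))
  }
  bad <- cbind(a = c(NA, NA), b = c(1, 2))
  expect_error(quantile_normalize(bad), "all-missing")
})

test_that("log2 fold change matches hand values and is antisymmetric", {
  v <- matrix(c(2, 2, 8, 8,
                4, 4, 4, 4,
                NA, NA, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("CTR_1", "CTR_2", "FSH_1", "FSH_2")))
  m <- abundance_matrix(v, c("CTR", "CTR", "FSH", "FSH"))
  fc <- log2_fold_change(m, "FSH", "CTR")
  expect_equal(fc$log2fc[fc$protein == "A"], 2)   # log2(8/2)
  expect_equal(fc$log2fc[fc$protein == "B"], 0)
  expect_false("C" %in% fc$protein)               # Venn track, excluded
  rev <- log2_fold_change(m, "CTR", "FSH")
  expect_equal(rev$log2fc, -fc$log2fc)
})

test_that("differential calls follow the strict threshold rule", {
  rec <- data.frame(protein = c("Semaphorin-7A", "Endoplasmin", "edge", "ns"),
                    log2fc = c(1.562129, -5.50561, 1.5, 0.3))
  out <- classify_differential(rec, threshold = 1.5)
  expect_identical(out$call, c("UP", "DOWN", "NS", "NS"))
  expect_error(classify_differential(rec, threshold = 0), "threshold")
})

test_that("z-score autoscaling centers and scales rows, dropping degenerates", {
  withr::with_seed(4, m <- matrix(rlnorm(30 * 5), 30, 5,
                                  dimnames = list(sprintf("P%02d", 1:30),
                                                  letters[1:5])))
  z <- zscore_autoscale(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  flat <- rbind(m, P31 = rep(2, 5))
  expect_warning(z2 <- zscore_autoscale(flat), "zero-variance")
  expect_false("P31" %in% rownames(z2))
  neg <- m; neg[1, 1] <- 0
  expect_error(zscore_autoscale(neg), "P01")
})

test_that("clustergram reproduces a hand agglomeration and is label-invariant", {
  # 1-D points {0, 1, 10}: average linkage merges (0,1) at 1, then at 9.5
  z <- cbind(a = c(0, 1, 10), b = c(0, 1, 10))
  rownames(z) <- c("r1", "r2", "r3")
  d <- stats::hclust(stats::dist(cbind(c(0, 1, 10))), method = "average")
  expect_equal(d$height, c(1, 9.5))
  cg <- clustergram(z, linkage = "average", metric = "euclidean")
  expect_equal(cg$row_tree$height / sqrt(2), c(1, 9.5))
  # identical rows merge first at height 0
  z2 <- rbind(z, r4 = c(0, 0))
  cg2 <- clustergram(z2)
  expect_equal(min(cg2$row_tree$height), 0)
  # permutation invariance of the merge heights
  withr::with_seed(5, zm <- matrix(rnorm(40), 10, 4,
                                   dimnames = list(sprintf("g%02d", 1:10),
                                                   letters[1:4])))
  perm <- withr::with_seed(6, sample(10))
  h1 <- clustergram(zm)$row_tree$height
  h2 <- clustergram(zm[perm, ])$row_tree$height
  expect_equal(h1, h2)
  expect_error(clustergram(matrix(c(1, NaN, 2, 3), 2)), "non-finite")
})

test_that("clustergram exports are plain text and parseable", {
  withr::with_seed(5, zm <- matrix(rnorm(40), 10, 4,
                                   dimnames = list(sprintf("g%02d", 1:10),
                                                   letters[1:4])))
  prefix <- file.path(withr::local_tempdir(), "cg")
  write_clustergram(clustergram(zm), prefix)
  z_back <- utils::read.table(paste0(prefix, "_zscores.tsv"), header = TRUE,
                              sep = "\t")
  expect_equal(as.matrix(z_back[, -1]), unname(zm), ignore_attr = TRUE,
               tolerance = 1e-6)
  tree <- ape::read.tree(paste0(prefix, "_rows.nwk"))
  expect_setequal(tree$tip.label, rownames(zm))
})
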