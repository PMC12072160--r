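#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the ratio of between-group to
#' within-group mean squares with its F-distribution p-value. Degenerate
#' inputs with zero within-group variance are handled explicitly: equal
#' group means give `F = 0, p = 1`; unequal means give an infinite F,
#' reported as the limiting `p = 0` with a flag.
#'
#' @param data Named list of numeric vectors (one per group), each
#'   nonempty, at least two groups, total n greater than the number of
#'   groups.
#' @return A list: `F`, `p`, `df` (numerator, denominator), `flag`
#'   (`NA` or `"zero_within_variance"`).
#' @export
one_way_anova <- function(data) {
  check_groups(data, min_groups = 2)
  k <- length(data)
  n <- sum(lengths(data))
  if (n <= k) stop("total n must exceed the number of groups")
  values <- unlist(data, use.names = FALSE)
  g <- factor(rep(names(data), lengths(data)), levels = names(data))
  ssw <- sum(vapply(data, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) {
    means <- vapply(data, mean, numeric(1))
    if (max(means) - min(means) == 0)
      return(list(F = 0, p = 1, df = c(k - 1, n - k), flag = NA_character_))
    return(list(F = Inf, p = 0, df = c(k - 1, n - k),
                flag = "zero_within_variance"))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter), flag = NA_character_)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Two-sample t-tests (pooled variance by default, Welch optional) for all
#' unordered pairs of groups, with each raw p-value multiplied by the
#' number of comparisons `choose(k, 2)` and capped at 1 — the classical
#' Bonferroni post hoc following a one-way ANOVA. Pairs involving a group
#' with fewer than two observations are skipped with a flag.
#'
#' @param data Named list of numeric vectors.
#' @param var_equal Pooled-variance t-test (`TRUE`, default) or Welch.
#' @return A data.frame: `group_a`, `group_b`, `p_raw`, `p_adj`, `flag`.
#' @export
bonferroni_pairwise <- function(data, var_equal = TRUE) {
  check_groups(data, min_groups = 2)
  k <- length(data)
  m <- choose(k, 2)
  pairs <- utils::combn(names(data), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (length(data[[a]]) < 2 || length(data[[b]]) < 2)
      return(data.frame(group_a = a, group_b = b, p_raw = NA_real_,
                        p_adj = NA_real_, flag = "group_too_small",
                        stringsAsFactors = FALSE))
    p <- stats::t.test(data[[a]], data[[b]], var.equal = var_equal)$p.value
    data.frame(group_a = a, group_b = b, p_raw = p,
               p_adj = min(1, p * m), flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median with a confidence interval
#'
#' The sample median with either a seeded percentile-bootstrap interval
#' (default, `B` resamples) or the distribution-free order-statistic
#' interval based on the binomial distribution of the number of
#' observations below the median (conservative: coverage at least the
#' nominal level). With fewer than three observations, the full data range
#' is reported with a flag.
#'
#' @param values Numeric vector (no missing values), `n >= 1`.
#' @param level Confidence level in `(0, 1)`.
#' @param method `"bootstrap"` or `"order_statistic"`.
#' @param B Number of bootstrap resamples.
#' @param seed Optional seed for the bootstrap.
#' @return A list: `median`, `lo`, `hi`, `method`, `flag`.
#' @export
median_ci <- function(values, level = 0.95,
                      method = c("bootstrap", "order_statistic"),
                      B = 2000, seed = NULL) {
  method <- match.arg(method)
  if (length(values) < 1 || any(is.na(values))) stop("need non-missing values")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  med <- stats::median(values)
  n <- length(values)
  if (n < 3)
    return(list(median = med, lo = min(values), hi = max(values),
                method = method, flag = "insufficient_n"))
  alpha <- 1 - level
  if (method == "bootstrap") {
    boot <- function() {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), n)
      apply(idx, 2, function(i) stats::median(values[i]))
    }
    meds <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
    qs <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    list(median = med, lo = qs[1], hi = qs[2], method = method,
         flag = NA_character_)
  } else {
    s <- sort(values)
    # largest l with P(X < l) <= alpha/2 under Binomial(n, 1/2)
    l <- stats::qbinom(alpha / 2, n, 0.5)
    if (stats::pbinom(l - 1, n, 0.5) > alpha / 2) l <- l - 1
    l <- max(l, 1)
    u <- n - l + 1
    list(median = med, lo = s[l], hi = s[u], method = method,
         flag = NA_character_)
  }
}

#' Full group comparison of a metric
#'
#' Convenience wrapper tying the group statistics together: one-way ANOVA,
#' Bonferroni pairwise comparisons, and per-group summaries (mean, SD,
#' median with CI).
#'
#' @param data Named list of numeric vectors, or a data.frame with `value`
#'   and `group` column names given.
#' @param value,group Column names when `data` is a data.frame.
#' @param conf_level Confidence level for the median CIs.
#' @param ci_method Passed to [median_ci()].
#' @param var_equal Passed to [bonferroni_pairwise()].
#' @param seed Seed for the bootstrap CIs.
#' @return A list of class `group_comparison`: `anova`, `pairwise`,
#'   `summaries`.
#' @export
compare_groups <- function(data, value = "amplitude", group = "condition",
                           conf_level = 0.95, ci_method = "bootstrap",
                           var_equal = TRUE, seed = NULL) {
  if (is.data.frame(data)) {
    v <- data[[value]]
    keep <- !is.na(v)
    data <- split(v[keep], data[[group]][keep])
  }
  check_groups(data, min_groups = 2)
  summaries <- do.call(rbind, lapply(names(data), function(gn) {
    v <- data[[gn]]
    ci <- median_ci(v, level = conf_level, method = ci_method, seed = seed)
    data.frame(group = gn, n = length(v), mean = mean(v),
               sd = stats::sd(v), median = ci$median, lo = ci$lo,
               hi = ci$hi, stringsAsFactors = FALSE)
  }))
  structure(list(anova = one_way_anova(data),
                 pairwise = bonferroni_pairwise(data, var_equal = var_equal),
                 summaries = summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  cat("pairwise (Bonferroni):\n")
  print(x$pairwise, row.names = FALSE)
  cat("group summaries:\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

check_groups <- function(data, min_groups = 2) {
  if (!is.list(data) || length(data) < min_groups)
    stop(sprintf("need at least %d groups", min_groups))
  if (is.null(names(data)) || anyDuplicated(names(data)))
    stop("groups must be uniquely named")
  if (any(lengths(data) == 0)) stop("every group must be nonempty")
  if (any(vapply(data, function(v) any(is.na(v)), logical(1))))
    stop("missing values in groups; remove them first")
  invisible(TRUE)
}
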