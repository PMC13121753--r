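#' Two-group mean comparison (t-test wrapper)
#'
#' Two-sided t-test with the reporting conventions used throughout:
#' unpaired comparisons default to Welch's unequal-variance form
#' (`var_equal = TRUE` selects the pooled-variance test), paired
#' comparisons pair by position. Degenerate inputs (zero variance of the
#' pairwise differences, or of both groups) are reported rather than
#' erroring: identical groups give statistic 0 and p = 1, a constant
#' non-zero paired difference gives p = 0; both are flagged.
#'
#' @param group_a,group_b Numeric vectors (equal length and matched order
#'   when `paired`).
#' @param paired Paired test (same embryo sampled twice)?
#' @param var_equal Pooled-variance instead of Welch for the unpaired test.
#' @param labels Length-2 group names for reporting.
#' @return A `comparison_result`: test name, group labels, n, statistic,
#'   two-sided p, mean and sem per group, pairing and degeneracy flags.
#' @export
compare_means <- function(group_a, group_b, paired = FALSE,
                          var_equal = FALSE,
                          labels = c("group_a", "group_b")) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_validation("need n >= 2 per group (got %d, %d)",
                    length(group_a), length(group_b))
  if (paired && length(group_a) != length(group_b))
    stop_validation("paired groups must have equal length")
  degenerate <- FALSE
  if (paired) {
    d <- group_a - group_b
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      statistic <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    }
  } else if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    degenerate <- TRUE
    dm <- mean(group_a) - mean(group_b)
    statistic <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  }
  if (!degenerate) {
    tt <- stats::t.test(group_a, group_b, paired = paired,
                        var.equal = var_equal, alternative = "two.sided")
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    test = if (paired) "paired t-test"
           else if (var_equal) "unpaired t-test (pooled)"
           else "unpaired t-test (Welch)",
    labels = labels,
    n = c(length(group_a), length(group_b)),
    statistic = statistic, p = p,
    mean = c(mean(group_a), mean(group_b)),
    sem = c(sem(group_a), sem(group_b)),
    paired = paired, degenerate = degenerate),
    class = "comparison_result")
}

#' Two-sample distribution comparison (Kolmogorov-Smirnov wrapper)
#'
#' Two-sided two-sample KS test: the statistic is the maximum absolute gap
#' between the two empirical CDFs.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 5 values.
#' @return A `comparison_result`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 5L || length(sample_b) < 5L)
    stop_validation("need n >= 5 per sample (got %d, %d)",
                    length(sample_a), length(sample_b))
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        alternative = "two.sided"))
  structure(list(test = "two-sample Kolmogorov-Smirnov",
                 labels = c("sample_a", "sample_b"),
                 n = c(length(sample_a), length(sample_b)),
                 statistic = unname(kt$statistic), p = kt$p.value,
                 mean = c(mean(sample_a), mean(sample_b)),
                 sem = c(sem(sample_a), sem(sample_b)),
                 paired = FALSE, degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d)\n", x$test,
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  means %.4g +/- %.3g and %.4g +/- %.3g\n",
              x$mean[1], x$sem[1], x$mean[2], x$sem[2]))
  cat(sprintf("  statistic %.4g, two-sided p %.4g %s%s\n", x$statistic, x$p,
              significance_stars(x$p),
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

#' Significance stars
#'
#' The reporting bands: ns for p > 0.05, then `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001 (p exactly 0.05 reads ns).
#'
#' @param p P-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Grouped mean +/- sem summary table
#'
#' @param values Numeric vector.
#' @param by Grouping vector (or list of vectors, interaction taken).
#' @return Data frame: `group`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(values, by) {
  if (is.list(by)) by <- interaction(by, drop = TRUE, sep = "/")
  by <- as.factor(by)
  parts <- split(values, by)
  data.frame(group = names(parts),
             n = lengths(parts),
             mean = vapply(parts, mean, numeric(1)),
             sem = vapply(parts, sem, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
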