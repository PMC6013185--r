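#' Two-group one-way ANOVA F-test for a single feature
#'
#' Computed directly from sums of squares: `F = MS_between / MS_within` with
#' degrees of freedom (1, n - 2), which for two groups is exactly the square
#' of the pooled-variance two-sample t statistic. If the within-group sum of
#' squares is zero, F is reported as `Inf` with p = 0 when the group means
#' differ and as 0 with p = 1 otherwise.
#'
#' @param values Numeric vector of one feature's intensities.
#' @param labels Two-group indicator, same length as `values`; each group
#'   must have at least 2 samples.
#' @return A list with elements `F`, `p` and `df` (a length-2 vector).
#' @export
#' @examples
#' anova_f_test(c(0, 1, 2, 3), c(1, 1, 2, 2))  # F = 8
anova_f_test <- function(values, labels) {
  res <- anova_screen(matrix(values, ncol = 1), labels, adjust = FALSE)
  list(F = res$F, p = res$p_raw, df = c(1, length(values) - 2))
}

.check_two_groups <- function(labels, n) {
  if (length(labels) != n) {
    stop("`labels` must have one entry per sample", call. = FALSE)
  }
  groups <- sort(unique(labels))
  if (length(groups) != 2) {
    stop("exactly two groups are required, got ", length(groups), call. = FALSE)
  }
  counts <- c(sum(labels == groups[1]), sum(labels == groups[2]))
  if (any(counts < 2)) {
    stop("degenerate design: each group needs at least 2 samples", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 samples in total", call. = FALSE)
  groups
}

#' Per-feature ANOVA screen with BH-FDR adjustment
#'
#' Runs the two-group one-way ANOVA F-test on every column of `values`,
#' adjusts the raw p-values with the Benjamini-Hochberg step-up procedure,
#' and flags the selections at the three standard thresholds: unadjusted
#' p < 0.05, FDR-adjusted p < 0.05 and FDR-adjusted p < 0.20 (strict
#' inequalities). All tests share one F computation vectorized over
#' features; no preprocessing or variance filtering is applied.
#'
#' @param values Samples x features numeric matrix.
#' @param labels Two-group indicator per sample (any two distinct values;
#'   sorted order defines groups 1 and 2).
#' @param adjust Apply the BH adjustment and selection flags (default); with
#'   `FALSE` only `F` and `p_raw` are returned, e.g. when the adjustment is
#'   to be applied per stratum afterwards.
#' @return A data frame with one row per feature: `feature_id`, `F`,
#'   `p_raw`, and (when `adjust = TRUE`) `p_adj`, `selected_raw05`,
#'   `selected_fdr05`, `selected_fdr20`.
#' @seealso [bh_adjust()], [select_features()]
#' @export
anova_screen <- function(values, labels, adjust = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  groups <- .check_two_groups(labels, n)
  g1 <- labels == groups[1]
  n1 <- sum(g1)
  n2 <- n - n1

  m1 <- colMeans(values[g1, , drop = FALSE])
  m2 <- colMeans(values[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums(sweep(values[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(values[!g1, , drop = FALSE], 2, m2)^2)

  msw <- ssw / (n - 2)
  f <- ifelse(ssw > 0, ssb / msw, ifelse(ssb > 0, Inf, 0))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)

  ids <- colnames(values)
  if (is.null(ids)) ids <- sprintf("F%0*d", nchar(ncol(values)), seq_len(ncol(values)))
  out <- data.frame(feature_id = ids, F = f, p_raw = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) {
    out$p_adj <- bh_adjust(p)
    out$selected_raw05 <- out$p_raw < 0.05
    out$selected_fdr05 <- out$p_adj < 0.05
    out$selected_fdr20 <- out$p_adj < 0.20
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: sorted
#' p-values are multiplied by `m / rank`, monotonicity is enforced by a
#' cumulative minimum from the largest rank down, values are capped at 1 and
#' returned in the original order. Adjusted values compared against a level
#' q reproduce the classical BH step-up selection at FDR q.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("`pvals` must be numeric", call. = FALSE)
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1] at position(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Threshold selection from an ANOVA screen
#'
#' Features are selected when the chosen p-value column is strictly smaller
#' than the threshold.
#'
#' @param result Data frame from [anova_screen()].
#' @param rule `"raw"` (unadjusted p-values) or `"fdr"` (BH-adjusted).
#' @param threshold Significance level in (0, 1).
#' @return Logical selection vector, one entry per feature.
#' @export
select_features <- function(result, rule = c("raw", "fdr"), threshold = 0.05) {
  rule <- match.arg(rule)
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single value in (0, 1)", call. = FALSE)
  }
  col <- if (rule == "raw") "p_raw" else "p_adj"
  if (is.null(result[[col]])) {
    stop("column `", col, "` not found; run anova_screen(..., adjust = TRUE)",
         call. = FALSE)
  }
  result[[col]] < threshold
}
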