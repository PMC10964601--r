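# Biomarker-region selection: a region is retained when it is in the top
# 10% of regions by the absolute between-group difference in mean rs-FCSM
# score (Difference_mean) AND not in the top 10% by the sum of the two
# groups' score standard deviations (Sum_std).  Selected regions are then
# validated with per-region ROC curves and Bonferroni-corrected two-sample
# t-tests.

#' Number of regions in a top fraction
#'
#' `ceiling(fraction * n_regions)`, so the top 10% of 116 regions is 12.
#'
#' @param n_regions Total number of regions.
#' @param fraction Fraction in (0, 1).
#' @return Integer count.
#' @export
top_fraction_count <- function(n_regions, fraction = 0.10) {
  stopifnot(n_regions >= 1L, fraction > 0, fraction < 1)
  as.integer(ceiling(fraction * n_regions))
}

# indices of the k largest values; ties broken by ascending index
top_k_indices <- function(values, k) {
  ord <- order(-values, seq_along(values))
  ord[seq_len(k)]
}

#' Two-sample t-test on a region's scores
#'
#' Two-sided independent-samples t-test.  The pooled equal-variance form is
#' the default; Welch's correction is available.
#'
#' @param x,y Numeric score vectors of the two groups (each n >= 2).
#' @param var_equal Pooled form if `TRUE` (default), Welch if `FALSE`.
#' @return List with `t` and `p`.  When the pooled variance is zero the
#'   test is undefined and both are `NA` with `degenerate = TRUE`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' ROC curve and AUC for a region's scores
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for ties:
#' `AUC = U / (n_pos * n_neg)`.  The curve is the usual step function over
#' descending score thresholds.  Orientation is fixed by the caller's
#' positive class; an AUC below 0.5 is reported as-is.
#'
#' @param scores_positive Scores of the positive class.
#' @param scores_negative Scores of the negative class.
#' @return List with `auc` and `curve`, a data frame of (fpr, tpr) step
#'   points starting at (0, 0) and ending at (1, 1).
#' @export
roc_auc <- function(scores_positive, scores_negative) {
  n1 <- length(scores_positive)
  n2 <- length(scores_negative)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(scores_positive, scores_negative))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  thr <- sort(unique(c(scores_positive, scores_negative)),
              decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_positive >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores_negative >= t), 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Select biomarker regions by the dual top-fraction rule
#'
#' Computes, per region, the absolute difference between the two groups'
#' mean Z scores (`difference_mean`) and the sum of their standard
#' deviations (`sum_std`); flags the top `ceiling(fraction * R)` regions of
#' each; and selects regions in the top set of `difference_mean` but not in
#' the top set of `sum_std`.  Each region also gets a two-sample t-test
#' (Bonferroni-corrected over `n_tests` regions) and the ROC AUC of its Z
#' scores with the excellent group as positive class.
#'
#' @param z_excellent Subjects x regions Z-score matrix of the
#'   excellent-cognition group (n >= 2).
#' @param z_poor Subjects x regions Z-score matrix of the poor-cognition
#'   group (n >= 2).
#' @param fraction Top fraction for both rankings, default 0.10.
#' @param n_tests Bonferroni multiplier; defaults to the region count
#'   (strict correction over all regions).
#' @param var_equal Passed to [two_sample_t()].
#' @return Data frame of class `region_selection` with one row per region:
#'   `region` (1-based index), `label`, `difference_mean`, `sum_std`,
#'   `in_top_diff`, `in_top_std`, `selected`, `t_statistic`, `p_raw`,
#'   `p_bonferroni`, `auc`.
#' @export
select_rois <- function(z_excellent, z_poor, fraction = 0.10,
                        n_tests = NULL, var_equal = TRUE) {
  z_excellent <- as.matrix(z_excellent)
  z_poor <- as.matrix(z_poor)
  R <- ncol(z_excellent)
  if (ncol(z_poor) != R) {
    stop("the two groups have different region counts (", R, " vs ",
         ncol(z_poor), ")", call. = FALSE)
  }
  if (nrow(z_excellent) < 2L || nrow(z_poor) < 2L) {
    stop("each group needs at least 2 subjects (standard deviation ",
         "undefined otherwise)", call. = FALSE)
  }
  if (is.null(n_tests)) n_tests <- R

  difference_mean <- abs(colMeans(z_excellent) - colMeans(z_poor))
  sum_std <- apply(z_excellent, 2L, stats::sd) +
    apply(z_poor, 2L, stats::sd)

  k <- top_fraction_count(R, fraction)
  in_top_diff <- seq_len(R) %in% top_k_indices(difference_mean, k)
  in_top_std <- seq_len(R) %in% top_k_indices(sum_std, k)
  selected <- in_top_diff & !in_top_std

  tests <- lapply(seq_len(R), function(i) {
    two_sample_t(z_excellent[, i], z_poor[, i], var_equal = var_equal)
  })
  aucs <- vapply(seq_len(R), function(i) {
    roc_auc(z_excellent[, i], z_poor[, i])$auc
  }, 0)
  p_raw <- vapply(tests, `[[`, 0, "p")

  labels <- colnames(z_excellent)
  if (is.null(labels)) labels <- sprintf("Region_%03d", seq_len(R))
  out <- data.frame(
    region = seq_len(R),
    label = labels,
    difference_mean = difference_mean,
    sum_std = sum_std,
    in_top_diff = in_top_diff,
    in_top_std = in_top_std,
    selected = selected,
    t_statistic = vapply(tests, `[[`, 0, "t"),
    p_raw = p_raw,
    p_bonferroni = pmin(1, p_raw * n_tests),
    auc = aucs,
    row.names = NULL
  )
  attr(out, "fraction") <- fraction
  attr(out, "top_k") <- k
  attr(out, "n_tests") <- n_tests
  class(out) <- c("region_selection", "data.frame")
  out
}

#' @export
print.region_selection <- function(x, ...) {
  sel <- x[x$selected, ]
  cat("<region_selection> ", nrow(x), " regions, top-k = ",
      attr(x, "top_k"), ", ", nrow(sel), " selected\n", sep = "")
  if (nrow(sel)) {
    print.data.frame(sel[, c("region", "label", "difference_mean",
                             "sum_std", "p_bonferroni", "auc")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Indices of selected biomarker regions
#'
#' @param selection A `region_selection` table.
#' @return Integer vector of 1-based region indices.
#' @export
selected_regions <- function(selection) {
  selection$region[selection$selected]
}
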