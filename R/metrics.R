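#' Classification metrics for a two-class score vector
#'
#' AUC is computed by the rank (Mann-Whitney) formulation — equivalent to
#' the concordant-pair fraction, with tied scores credited 0.5. Accuracy,
#' sensitivity (positive-class recall), and specificity come from the
#' thresholded confusion table.
#'
#' @param scores Numeric class-1 scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold (class 1 on `>=`; default 0.5).
#' @param positive_class Label treated as positive (default 1).
#' @return An object of class `metric_set`: `AUC`, `ACC`, `SEN`, `SPE`, and
#'   confusion counts `TP`, `FP`, `TN`, `FN`. With single-class labels AUC
#'   is `NA` (undefined); the thresholded metrics are still computed.
#' @export
#' @examples
#' compute_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$AUC  # 0.75
compute_metrics <- function(scores, labels, threshold = 0.5, positive_class = 1) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_class
  n1 <- sum(pos)
  n0 <- sum(!pos)
  auc <- if (n1 == 0 || n0 == 0) {
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & pos)
  fp <- sum(pred_pos & !pos)
  tn <- sum(!pred_pos & !pos)
  fn <- sum(!pred_pos & pos)
  structure(
    list(
      AUC = auc,
      ACC = (tp + tn) / length(labels),
      SEN = if (n1 > 0) tp / n1 else NA_real_,
      SPE = if (n0 > 0) tn / n0 else NA_real_,
      TP = tp, FP = fp, TN = tn, FN = fn,
      positive_class = positive_class, threshold = threshold
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> AUC %.3f, ACC %.3f, SEN %.3f, SPE %.3f\n",
              x$AUC, x$ACC, x$SEN, x$SPE))
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided paired signed-rank test (significance conventionally at
#' p < 0.05). Zero differences are dropped per the signed-rank convention;
#' if every difference is zero the comparison is degenerate and flagged
#' rather than tested.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A list with `statistic`, `p_value`, `n_effective` (pairs after
#'   dropping zero differences), and `degenerate`.
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_effective = 0L,
                degenerate = TRUE))
  }
  if (nz < 5) {
    warning("fewer than 5 non-zero differences; test is underpowered",
            call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = as.integer(nz), degenerate = FALSE)
}
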