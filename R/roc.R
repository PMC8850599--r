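# ROC biomarker evaluation by the rank method (ties counted half), with
# automatic orientation so the reported AUC is always >= 0.5.

#' ROC curve and AUC for one marker
#'
#' The AUC is computed by the rank (Mann-Whitney) method with ties counted
#' half, i.e. the probability that a random case scores above a random
#' control plus half the probability of a tie. If the raw AUC is below 0.5
#' the scores are negated (markers may discriminate in either direction) and
#' the `flipped` flag records the re-orientation. The curve is the standard
#' step function over score thresholds, returned in increasing-FPR order
#' from (0, 0) to (1, 1).
#'
#' @param values Numeric marker values, one per subject.
#' @param case_labels Logical vector (`TRUE` = case) or a vector of labels
#'   combined with `case_label`.
#' @param case_label When `case_labels` is not logical, the label denoting a
#'   case (default `"PD"`).
#' @return Object of class `roc_result`: list with `auc`, `flipped`,
#'   `curve` (data.frame `threshold`, `fpr`, `tpr`), `n_case`, `n_control`.
#' @examples
#' roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_curve <- function(values, case_labels, case_label = "PD") {
  values <- as.numeric(values)
  if (!is.logical(case_labels)) case_labels <- case_labels == case_label
  assert_that(length(values) == length(case_labels),
              "values and case_labels must have equal length")
  ok <- is.finite(values) & !is.na(case_labels)
  values <- values[ok]; case_labels <- case_labels[ok]
  n1 <- sum(case_labels); n0 <- sum(!case_labels)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")

  auc_of <- function(v) {
    r <- rank(v)
    (sum(r[case_labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(values)
  flipped <- auc < 0.5
  if (flipped) {
    values <- -values
    auc <- auc_of(values)
  }

  thresholds <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(values[case_labels] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(values[!case_labels] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thresholds),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  rownames(curve) <- NULL

  structure(list(auc = auc, flipped = flipped, curve = curve,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d cases vs %d controls)%s\n", x$auc,
              x$n_case, x$n_control,
              if (x$flipped) ", scores re-oriented" else ""))
  invisible(x)
}
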