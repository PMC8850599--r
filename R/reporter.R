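# Dual-luciferase reporter analytics: per-well signal/control normalization
# and condition-vs-reference inhibition testing.
#
# In the psiCHECK-2 design the tested fragment is fused to the Renilla
# luciferase 3' UTR, and the constitutive firefly luciferase normalizes
# transfection efficiency; "signal" therefore defaults to Renilla. The
# `signal` switch accommodates vectors with the opposite arrangement.

#' Normalize dual-luciferase plate readings
#'
#' Per-well ratio `R = signal / control`, with per-condition mean and SD.
#' Blank wells (condition `"blank"`) are excluded from ratio analysis.
#'
#' @param wells data.frame with columns `condition`, `replicate`,
#'   `renilla`, `firefly` (luminescence, arbitrary units; must be positive
#'   for non-blank wells).
#' @param signal Which luciferase carries the insert: `"renilla"` (default,
#'   psiCHECK-2 design) or `"firefly"`.
#' @return List of class `reporter_normalized`: `per_well` (condition,
#'   replicate, ratio) and `per_condition` (condition, n, mean_ratio,
#'   sd_ratio).
#' @export
normalize_reporter <- function(wells, signal = c("renilla", "firefly")) {
  signal <- match.arg(signal)
  need <- c("condition", "replicate", "renilla", "firefly")
  assert_that(all(need %in% names(wells)),
              "wells needs columns condition, replicate, renilla, firefly")
  live <- wells[wells$condition != "blank", , drop = FALSE]
  assert_that(nrow(live) > 0, "no non-blank wells")

  ctrl_channel <- if (signal == "renilla") "firefly" else "renilla"
  bad <- which(!(live[[signal]] > 0) | !(live[[ctrl_channel]] > 0))
  if (length(bad)) {
    stop(sprintf("non-positive luminescence in well (condition %s, replicate %s)",
                 live$condition[bad[1]], live$replicate[bad[1]]), call. = FALSE)
  }
  counts <- table(live$condition)
  if (any(counts < 2)) {
    stop(sprintf("condition '%s' has fewer than 2 replicate wells",
                 names(counts)[which(counts < 2)[1]]), call. = FALSE)
  }

  per_well <- data.frame(condition = live$condition, replicate = live$replicate,
                         ratio = live[[signal]] / live[[ctrl_channel]],
                         stringsAsFactors = FALSE)
  conds <- unique(per_well$condition)
  per_condition <- data.frame(
    condition = conds,
    n = vapply(conds, function(cn) sum(per_well$condition == cn), integer(1)),
    mean_ratio = vapply(conds, function(cn) mean(per_well$ratio[per_well$condition == cn]), numeric(1)),
    sd_ratio = vapply(conds, function(cn) stats::sd(per_well$ratio[per_well$condition == cn]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per_condition) <- NULL
  structure(list(per_well = per_well, per_condition = per_condition,
                 signal = signal),
            class = "reporter_normalized")
}

#' Compare reporter conditions against a reference
#'
#' Percent change of each condition's mean normalized activity versus the
#' reference (`100 * (1 - mean_R_condition / mean_R_reference)`; positive =
#' inhibition), with an unpaired two-sample t test on the replicate ratios.
#' Under a planted inhibition the wild-type construct is expected
#' significant and the seed-mutated construct non-significant.
#'
#' @param normalized Result of [normalize_reporter()].
#' @param reference_condition Reference condition label (default `"NC"`).
#' @param alpha Significance level (default 0.05).
#' @return data.frame: `condition`, `n`, `mean_ratio`, `pct_change`,
#'   `statistic`, `p_value`, `significant`.
#' @export
compare_reporter_conditions <- function(normalized, reference_condition = "NC",
                                        alpha = 0.05) {
  assert_that(inherits(normalized, "reporter_normalized"),
              "normalized must come from normalize_reporter()")
  pw <- normalized$per_well
  assert_that(reference_condition %in% pw$condition,
              sprintf("reference condition '%s' not present", reference_condition))
  ref <- pw$ratio[pw$condition == reference_condition]
  ref_mean <- mean(ref)

  conds <- setdiff(unique(pw$condition), reference_condition)
  rows <- lapply(conds, function(cn) {
    v <- pw$ratio[pw$condition == cn]
    if (stats::sd(v) == 0 && stats::sd(ref) == 0) {
      # degenerate noise-free plate: any difference of means is exact
      stat <- if (mean(v) == ref_mean) 0 else sign(mean(v) - ref_mean) * Inf
      pval <- if (mean(v) == ref_mean) 1 else 0
    } else {
      tt <- stats::t.test(v, ref, var.equal = TRUE)
      stat <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(condition = cn, n = length(v), mean_ratio = mean(v),
               pct_change = 100 * (1 - mean(v) / ref_mean),
               statistic = stat, p_value = pval,
               significant = pval < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
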