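# Adaptive group-comparison engine: a D'Agostino-Pearson normality gate
# routing each marker to a parametric (t / one-way ANOVA + Tukey) or
# nonparametric (Mann-Whitney / Kruskal-Wallis + Dunn) branch, mirroring the
# workflow of desktop statistics suites used for qRT-PCR panels.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected skewness z (D'Agostino 1970) and
#' kurtosis z (Anscombe-Glynn 1983) into the K-squared omnibus statistic,
#' referred to a chi-squared distribution with 2 df. The transforms are
#' unreliable below n = 8, which is therefore the minimum accepted.
#'
#' @param x Numeric vector, `length(x) >= 8`.
#' @return List with `statistic` (K squared), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  assert_that(n >= 8, "dagostino_pearson requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  assert_that(m2 > 0, "dagostino_pearson requires non-constant data")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5   # sample skewness (biased moments)
  b2 <- m4 / m2^2     # sample kurtosis

  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- if (y == 0) 0 else delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xx * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z_k <- (term1 - term2) / sqrt(2 / (9 * a))

  k2 <- z_s^2 + z_k^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z_s, z_kurtosis = z_k, n = n)
}

#' Choose the comparison test for a set of groups
#'
#' Parametric branch (unpaired t for two groups; ordinary one-way ANOVA with
#' Tukey post hoc for three or more) iff every group has at least
#' `min_n_for_normality` observations *and* passes the D'Agostino-Pearson
#' test at `alpha_normality`; otherwise the nonparametric branch
#' (Mann-Whitney; Kruskal-Wallis with Dunn post hoc). A pure, deterministic
#' function of its inputs.
#'
#' @param groups_of_values Named list of numeric vectors, one per group; at
#'   least 2 groups with at least 3 values each.
#' @param alpha_normality Significance level of the normality gate
#'   (default 0.05).
#' @param min_n_for_normality Minimum per-group n for the normality test to
#'   be attempted (default 8; smaller groups route nonparametric).
#' @return One of `"unpaired t"`, `"Mann-Whitney"`,
#'   `"ordinary one-way ANOVA + Tukey"`, `"Kruskal-Wallis + Dunn"`.
#' @export
select_test <- function(groups_of_values, alpha_normality = 0.05,
                        min_n_for_normality = 8) {
  assert_that(is.list(groups_of_values) && length(groups_of_values) >= 2,
              "need at least 2 groups")
  ns <- lengths(groups_of_values)
  if (any(ns < 3)) {
    stop(sprintf("every group needs >= 3 values (got %s)",
                 paste(ns, collapse = ", ")), call. = FALSE)
  }
  parametric <- all(ns >= min_n_for_normality) &&
    all(vapply(groups_of_values,
               function(g) dagostino_pearson(g)$p_value > alpha_normality,
               logical(1)))
  if (length(groups_of_values) == 2) {
    if (parametric) "unpaired t" else "Mann-Whitney"
  } else {
    if (parametric) "ordinary one-way ANOVA + Tukey" else "Kruskal-Wallis + Dunn"
  }
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise mean-rank comparisons on the joint ranking with tie correction;
#' p-values are Bonferroni-adjusted over the number of pairwise comparisons
#' (Dunn's classical family-wise control).
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame with one row per pair: `comparison`, `mean_rank_diff`
#'   (second minus first group), `z`, `p_value` (adjusted).
#' @export
dunn_posthoc <- function(groups) {
  k <- length(groups)
  assert_that(k >= 2, "need at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, labels, mean)
  ns <- tapply(r, labels, length)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    diff <- mean_ranks[[j]] - mean_ranks[[i]]
    z <- diff / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = sprintf("%s vs. %s", i, j),
               mean_rank_diff = diff, z = z,
               p_value = min(1, p_raw * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' qPCR statistical configuration
#'
#' @param alpha Significance level for group comparisons (default 0.05).
#' @param alpha_normality Level of the normality gate (default 0.05).
#' @param min_n_for_normality Minimum per-group n to attempt the normality
#'   test (default 8).
#' @param p_adjust Multiple-testing correction across markers in
#'   [marker_report()]: `"none"` (default) or `"BH"`.
#' @return A list of class `qpcr_config`.
#' @export
qpcr_config <- function(alpha = 0.05, alpha_normality = 0.05,
                        min_n_for_normality = 8, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  structure(list(alpha = alpha, alpha_normality = alpha_normality,
                 min_n_for_normality = min_n_for_normality,
                 p_adjust = p_adjust),
            class = "qpcr_config")
}

comparison_row <- function(comparison, test_name, statistic, p_value, effect,
                           ci_low, ci_high, alpha) {
  data.frame(comparison = comparison, test_name = test_name,
             statistic = statistic, p_value = p_value, effect = effect,
             ci_low = ci_low, ci_high = ci_high,
             significant = is.finite(p_value) & p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Compare marker values across groups with the adaptive test
#'
#' For two groups, returns one comparison chosen by [select_test()]: an
#' unpaired (pooled-variance) t test with mean difference and 95% CI, or a
#' Mann-Whitney test with the Hodges-Lehmann median difference and its
#' distribution-free 95% CI. For three or more groups, returns the omnibus
#' test plus all pairwise post hoc comparisons (Tukey HSD mean differences
#' with family-wise CIs, or Dunn mean-rank differences without CIs).
#'
#' Effects are always oriented as *second group minus first group* of the
#' comparison label.
#'
#' @param marker_values_by_group Named list of numeric vectors.
#' @param config A [qpcr_config()].
#' @return data.frame with columns `comparison`, `test_name`, `statistic`,
#'   `p_value`, `effect`, `ci_low`, `ci_high`, `significant`.
#' @export
compare_groups <- function(marker_values_by_group, config = qpcr_config()) {
  groups <- marker_values_by_group
  assert_that(is.list(groups) && !is.null(names(groups)) && all(nzchar(names(groups))),
              "groups must be a named list")
  assert_that(!anyDuplicated(names(groups)), "group labels must be unique")
  test <- select_test(groups, config$alpha_normality, config$min_n_for_normality)
  alpha <- config$alpha

  if (length(groups) == 2) {
    a <- names(groups)[1]; b <- names(groups)[2]
    lab <- sprintf("%s vs. %s", a, b)
    if (test == "unpaired t") {
      tt <- stats::t.test(groups[[b]], groups[[a]], var.equal = TRUE,
                          conf.level = 0.95)
      res <- comparison_row(lab, test, unname(tt$statistic), tt$p.value,
                            unname(diff(rev(tt$estimate))), tt$conf.int[1],
                            tt$conf.int[2], alpha)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(groups[[b]], groups[[a]],
                                                conf.int = TRUE, conf.level = 0.95))
      res <- comparison_row(lab, test, unname(wt$statistic), wt$p.value,
                            unname(wt$estimate), wt$conf.int[1], wt$conf.int[2],
                            alpha)
    }
    return(res)
  }

  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (test == "ordinary one-way ANOVA + Tukey") {
    fit <- stats::aov(values ~ fac)
    an <- summary(fit)[[1]]
    omnibus <- comparison_row("omnibus", test, an[["F value"]][1],
                              an[["Pr(>F)"]][1], NA_real_, NA_real_, NA_real_,
                              alpha)
    tk <- stats::TukeyHSD(fit, conf.level = 0.95)$fac
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    post <- lapply(pairs, function(p) {
      key <- sprintf("%s-%s", p[2], p[1])   # TukeyHSD labels later-minus-earlier
      row <- tk[key, ]
      comparison_row(sprintf("%s vs. %s", p[1], p[2]), "Tukey HSD", NA_real_,
                     row[["p adj"]], row[["diff"]], row[["lwr"]], row[["upr"]],
                     alpha)
    })
    res <- rbind(omnibus, do.call(rbind, post))
  } else {
    kw <- stats::kruskal.test(values, fac)
    omnibus <- comparison_row("omnibus", test, unname(kw$statistic), kw$p.value,
                              NA_real_, NA_real_, NA_real_, alpha)
    dn <- dunn_posthoc(groups)
    post <- comparison_row(dn$comparison, "Dunn", dn$z, dn$p_value,
                           dn$mean_rank_diff, NA_real_, NA_real_, alpha)
    res <- rbind(omnibus, post)
  }
  rownames(res) <- NULL
  res
}
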