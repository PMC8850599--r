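test_that("D'Agostino-Pearson omnibus matches frozen reference values", {
  # reference values computed independently with scipy.stats.normaltest
  r <- dagostino_pearson(c(1:9, 50))
  expect_equal(r$statistic, 26.1832407221, tolerance = 1e-9)
  expect_equal(r$p_value, 2.0624e-06, tolerance = 1e-4)

  x <- c(-0.56047565, -0.23017749, 1.55870831, 0.07050839, 0.12928774,
         1.71506499, 0.46091621, -1.26506123, -0.68685285, -0.44566197,
         1.22408180, 0.35981383, 0.40077145, 0.11068272, -0.55584113,
         1.78691314, 0.49785048, -1.96661716, 0.70135941, -0.47279141)
  r2 <- dagostino_pearson(x)
  expect_equal(r2$statistic, 0.0791601380, tolerance = 1e-4)
  expect_equal(r2$p_value, 0.9611929892, tolerance = 1e-5)

  expect_error(dagostino_pearson(rnorm(7)), "at least 8")
})

test_that("adaptive selection routes Gaussian data parametric, heavy tails nonparametric", {
  set.seed(42)
  g1 <- rnorm(20); g2 <- rnorm(20, 1)
  expect_identical(select_test(list(a = g1, b = g2)), "unpaired t")
  set.seed(43)
  h1 <- rlnorm(20, sdlog = 1.5); h2 <- rlnorm(20, 1, sdlog = 1.5)
  expect_identical(select_test(list(a = h1, b = h2)), "Mann-Whitney")
  # oracle check: the branch agrees with the normality gate run directly
  gate <- all(vapply(list(h1, h2), function(g) dagostino_pearson(g)$p_value > 0.05,
                     logical(1)))
  expect_false(gate)
  set.seed(44)
  expect_identical(select_test(list(a = rnorm(20), b = rnorm(20), c = rnorm(20))),
                   "ordinary one-way ANOVA + Tukey")
  expect_identical(select_test(list(a = rlnorm(20, sdlog = 2), b = rnorm(20),
                                    c = rnorm(20))), "Kruskal-Wallis + Dunn")
  # small groups bypass the normality test and go nonparametric
  expect_identical(select_test(list(a = rnorm(5), b = rnorm(5))), "Mann-Whitney")
  expect_error(select_test(list(a = 1:2, b = 1:10)), ">= 3 values")
})

test_that("Mann-Whitney branch reproduces the exact rank-permutation p-value", {
  res <- compare_groups(list(a = c(1, 2, 3, 4, 5), b = c(6, 7, 8, 9, 10)))
  expect_identical(res$test_name, "Mann-Whitney")
  # U = 25 for b vs a (all pairs concordant); exact two-sided p = 2/choose(10,5)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(res$effect > 0)   # second group minus first
  expect_true(res$significant)
})

test_that("identical groups give null effects and non-significance", {
  set.seed(7)
  g <- rnorm(15)
  res <- compare_groups(list(a = g, b = g))
  expect_equal(res$effect, 0, tolerance = 1e-9)
  expect_true(res$p_value > 0.9)
  expect_false(res$significant)
})

test_that("two-group parametric branch reports mean difference with 95% CI", {
  set.seed(8)
  a <- rnorm(20, 10, 1); b <- rnorm(20, 12, 1)
  res <- compare_groups(list(ctrl = a, case = b))
  expect_identical(res$test_name, "unpaired t")
  expect_equal(res$effect, mean(b) - mean(a), tolerance = 1e-12)
  expect_true(res$ci_low < res$effect && res$effect < res$ci_high)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("three-group parametric branch returns omnibus plus all Tukey pairs", {
  set.seed(1)
  gr <- list(A = rnorm(12, 0), B = rnorm(12, 1), C = rnorm(12, 2))
  expect_identical(select_test(gr), "ordinary one-way ANOVA + Tukey")
  res <- compare_groups(gr)
  expect_identical(nrow(res), 4L)
  expect_identical(res$comparison[1], "omnibus")
  expect_setequal(res$comparison[-1], c("A vs. B", "A vs. C", "B vs. C"))
  # effects are second-minus-first group means
  ab <- res[res$comparison == "A vs. B", ]
  expect_equal(ab$effect, mean(gr$B) - mean(gr$A), tolerance = 1e-9)
  expect_true(all(res$ci_low[-1] < res$effect[-1] & res$effect[-1] < res$ci_high[-1]))
})

test_that("nonparametric three-group branch returns Kruskal-Wallis plus Dunn ranks", {
  set.seed(10)
  gr <- list(A = rlnorm(12, sdlog = 2), B = rlnorm(12, 1.5, sdlog = 2),
             C = rlnorm(12, 3, sdlog = 2))
  res <- compare_groups(gr)
  expect_identical(res$test_name[1], "Kruskal-Wallis + Dunn")
  expect_identical(res$test_name[-1], rep("Dunn", 3))
  kw <- kruskal.test(unlist(gr), factor(rep(names(gr), lengths(gr))))
  expect_equal(res$p_value[1], kw$p.value, tolerance = 1e-12)
  # Dunn mean-rank differences recomputed directly from the joint ranking
  r <- rank(unlist(gr))
  lab <- rep(names(gr), lengths(gr))
  mr <- tapply(r, lab, mean)
  ac <- res[res$comparison == "A vs. C", ]
  expect_equal(ac$effect, unname(mr["C"] - mr["A"]), tolerance = 1e-9)
  expect_true(all(is.na(res$ci_low[-1])))   # rank-scale effects carry no CI
})

test_that("Dunn adjusted p-values are Bonferroni-bounded and ordered by |z|", {
  set.seed(12)
  gr <- list(A = rnorm(10), B = rnorm(10, 3), C = rnorm(10, 3))
  dn <- dunn_posthoc(gr)
  expect_true(all(dn$p_value <= 1))
  raw <- 2 * pnorm(-abs(dn$z))
  expect_equal(dn$p_value, pmin(1, raw * 3), tolerance = 1e-12)
})
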