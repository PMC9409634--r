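table1_counts <- function(yes, n) {
  rep(rep(c(1, 0), 3), c(yes[1], n[1] - yes[1], yes[2], n[2] - yes[2],
                         yes[3], n[3] - yes[3]))
}
table1_groups <- function(n) rep(c("NAV", "AVSc", "AVSt"), n)

test_that("normality gate passes Gaussian groups and fails skewed ones", {
  set.seed(90)
  normal_hits <- replicate(20, {
    group_normality(rnorm(600), rep(1:3, each = 200))$normal
  })
  expect_gte(mean(normal_hits), 0.9)
  expo_hits <- replicate(20, {
    group_normality(rexp(600), rep(1:3, each = 200))$normal
  })
  expect_equal(mean(expo_hits), 0)
})

test_that("groups below n = 8 are inconclusive and force non-normal", {
  res <- group_normality(c(rnorm(5), rnorm(200), rnorm(200)),
                         rep(1:3, c(5, 200, 200)))
  expect_true(res$inconclusive[1])
  expect_false(res$normal)
})

test_that("chi-square on printed three-group counts matches published p", {
  g <- table1_groups(c(22, 73, 32))
  smoking <- omnibus_test(table1_counts(c(6, 26, 12), c(22, 73, 32)), g,
                          type = "categorical")
  expect_equal(round(smoking$p, 3), 0.714)
  female <- omnibus_test(table1_counts(c(10, 40, 11), c(22, 73, 32)), g,
                         type = "categorical")
  expect_equal(female$p, 0.150, tolerance = 0.005)
  hyp <- omnibus_test(table1_counts(c(2, 4, 16), c(22, 73, 32)), g,
                      type = "categorical")
  expect_lt(hyp$p, 0.001)
})

test_that("identical groups degenerate to p = 1 with a flag", {
  res <- omnibus_test(rep(5, 60), rep(1:3, each = 20), type = "continuous")
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
})

test_that("omnibus routes by the normality gate", {
  set.seed(91)
  x <- rnorm(600)
  g <- rep(1:3, each = 200)
  expect_equal(omnibus_test(x, g, type = "continuous")$test, "ANOVA")
  expect_equal(omnibus_test(exp(x), g, type = "continuous")$test,
               "Kruskal-Wallis")
})

test_that("omnibus p is invariant to permuting the rows", {
  set.seed(92)
  x <- rexp(300)
  g <- rep(1:3, each = 100)
  p1 <- omnibus_test(x, g, type = "continuous")$p
  ord <- sample(300)
  p2 <- omnibus_test(x[ord], g[ord], type = "continuous")$p
  expect_equal(p1, p2)
})

test_that("empty groups are excluded with a warning", {
  x <- c(rnorm(40), rep(NA, 20))
  g <- rep(1:3, c(20, 20, 20))
  expect_warning(res <- omnibus_test(x, g, type = "continuous"), "empty")
  expect_true(is.finite(res$p))
})

test_that("Bonferroni per-comparison threshold is 0.017 for three pairs", {
  expect_equal(bonferroni_threshold(3), 0.017)
  expect_equal(bonferroni_threshold(2), 0.025)
})

test_that("post hoc flags demand omnibus significance and adjusted p", {
  set.seed(93)
  x <- c(rnorm(50, 0), rnorm(50, 2), rnorm(50, 0))  # 2-SD separation
  g <- rep(c("a", "b", "c"), each = 50)
  omni <- omnibus_test(x, g, type = "continuous")
  ph <- posthoc_tests(x, g, type = "continuous", omnibus_p = omni$p)
  expect_true(ph$significant[ph$group1 == "a" & ph$group2 == "b"])
  # identical pair never flags
  same <- posthoc_tests(rep(c(1, 2), 60), rep(c("a", "b", "c"), 40),
                        type = "continuous", omnibus_p = 0.001)
  expect_false(any(same$significant[same$test == "degenerate"]))
  # without omnibus significance nothing flags
  ph0 <- posthoc_tests(x, g, type = "continuous", omnibus_p = 0.2)
  expect_false(any(ph0$significant))
})

test_that("summary cells format by distribution style", {
  expect_equal(format_summary(c(1, 2, 3), "mean_sd")$label, "2.0 ± 1.0")
  m <- format_summary(c(1, 2, 3, 4), "median_iqr")
  expect_equal(m$median, 2.5)
  expect_equal(m$p25, 1.75)
  expect_equal(m$p75, 3.25)
  cp <- format_summary(rep(c(1, 0), c(16, 16)), "count_pct")
  expect_equal(cp$label, "16 (50%)")
})

test_that("compare_groups assembles a full comparison table", {
  sim <- simulate_cohort(seed = 77)
  tab <- compare_groups(sim$cohort, vars = c("age", "sbp", "smoking", "ava"))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$type[tab$variable == "smoking"], "categorical")
  expect_true(all(c("summary_NAV", "summary_AVSc", "summary_AVSt",
                    "p_NAV_vs_AVSc", "sig_AVSc_vs_AVSt") %in% names(tab)))
  # severe stenosis must separate the valve area
  expect_lt(tab$p[tab$variable == "ava"], 0.001)
  # group sizes propagate
  expect_equal(tab$n_NAV[tab$variable == "age"], 22)
})
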