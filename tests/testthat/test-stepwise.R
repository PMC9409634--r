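test_that("a strong single effect is recovered exactly", {
  set.seed(70)
  for (i in 1:5) {
    d <- data.frame(matrix(rnorm(200 * 5), 200, 5))
    names(d) <- paste0("x", 1:5)
    d$y <- 2 * d$x1 + rnorm(200)
    sel <- stepwise_select(d, "y", paste0("x", 1:5))
    expect_identical(sel$selected, "x1")
  }
})

test_that("null designs keep the analytic empty-selection rate", {
  # with five independent noise candidates the chance that none clears
  # p_enter = 0.05 is 0.95^5 = 0.774; check within binomial tolerance
  set.seed(71)
  empty <- replicate(150, {
    d <- data.frame(matrix(rnorm(200 * 5), 200, 5))
    names(d) <- paste0("x", 1:5)
    d$y <- rnorm(200)
    length(stepwise_select(d, "y", paste0("x", 1:5))$selected) == 0
  })
  p0 <- 0.95^5
  se <- sqrt(p0 * (1 - p0) / 150)
  expect_lt(abs(mean(empty) - p0), 3.5 * se)
})

test_that("a constant response selects nothing", {
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50), y = rep(1, 50))
  sel <- stepwise_select(d, "y", c("x1", "x2"))
  expect_length(sel$selected, 0)
})

test_that("zero-variance candidates are dropped with a warning", {
  set.seed(72)
  d <- data.frame(x1 = rnorm(100), x2 = rep(3, 100))
  d$y <- d$x1 + rnorm(100, sd = 0.2)
  expect_warning(sel <- stepwise_select(d, "y", c("x1", "x2")), "x2")
  expect_identical(sel$selected, "x1")
})

test_that("selection and step log are deterministic", {
  set.seed(73)
  d <- data.frame(matrix(rnorm(120 * 4), 120, 4))
  names(d) <- paste0("x", 1:4)
  d$y <- d$x1 - 0.8 * d$x3 + rnorm(120)
  a <- stepwise_select(d, "y", paste0("x", 1:4))
  b <- stepwise_select(d, "y", paste0("x", 1:4))
  expect_identical(a$selected, b$selected)
  expect_identical(tidy(a), tidy(b))
  expect_true(all(tidy(a)$action %in% c("add", "remove")))
})

test_that("small complete-case n reduces the candidate set with a warning", {
  set.seed(74)
  d <- data.frame(matrix(rnorm(18 * 10), 18, 10))
  names(d) <- paste0("x", 1:10)
  d$y <- d$x1 + rnorm(18, sd = 0.3)
  expect_warning(sel <- stepwise_select(d, "y", paste0("x", 1:10)),
                 "reducing")
  expect_lte(length(sel$candidates), 8)
  expect_true("x1" %in% sel$candidates)
})

test_that("missing data fall back to complete cases", {
  set.seed(75)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  d$y <- d$x1 + rnorm(100, sd = 0.5)
  d$x2[1:10] <- NA
  sel <- stepwise_select(d, "y", c("x1", "x2"))
  expect_equal(sel$n, 90)
})

test_that("per-category selections combine into a stable, bounded union", {
  combined <- assemble_predictors(list(valve = "pg_mean",
                                       clinical = c("age", "delta_mean_nn"),
                                       mbf = character(0)))
  expect_identical(combined, c("pg_mean", "age", "delta_mean_nn"))
  eleven <- assemble_predictors(list(a = paste0("v", 1:6),
                                     b = paste0("w", 1:5)))
  expect_length(eleven, 11)
  expect_error(assemble_predictors(list(a = paste0("v", 1:13))),
               class = "hrvpart_budget_error")
  # duplicates collapse
  expect_identical(assemble_predictors(list(c("a", "b"), c("b", "c"))),
                   c("a", "b", "c"))
})

test_that("glance summarizes a selection object", {
  set.seed(76)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  d$y <- d$x1 + rnorm(80)
  sel <- stepwise_select(d, "y", c("x1", "x2"))
  g <- glance(sel)
  expect_equal(g$n, 80)
  expect_true("x1" %in% sel$selected)
  expect_equal(g$n_selected, length(sel$selected))
})
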