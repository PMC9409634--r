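test_that("single-predictor subsets are 0 and the squared correlation", {
  set.seed(80)
  d <- data.frame(y = rnorm(50), x1 = rnorm(50))
  tab <- all_subsets_r2(d, "y", "x1")
  expect_equal(tab$r2[tab$subset == 0], 0)
  expect_equal(tab$r2[tab$subset == 1], cor(d$y, d$x1)^2, tolerance = 1e-12)
})

test_that("orthogonal standardized predictors add their R2 exactly", {
  set.seed(81)
  raw <- matrix(rnorm(100 * 2), 100, 2)
  X <- qr.Q(qr(cbind(1, raw)))[, 2:3]  # orthogonal, zero-mean columns
  d <- data.frame(y = X %*% c(1, 0.5) + rnorm(100), x1 = X[, 1],
                  x2 = X[, 2])
  tab <- all_subsets_r2(d, "y", c("x1", "x2"))
  expect_equal(tab$r2[tab$subset == 3],
               tab$r2[tab$subset == 1] + tab$r2[tab$subset == 2],
               tolerance = 1e-10)
  hp <- hier_partition(d, "y", c("x1", "x2"))
  expect_equal(hp$result$joint, c(0, 0), tolerance = 1e-10)
  expect_equal(hp$result$independent,
               c(tab$r2[tab$subset == 1], tab$r2[tab$subset == 2]),
               tolerance = 1e-10)
})

test_that("every subset R2 matches an independent lm refit", {
  d <- random_design(60, 3, seed = 82)
  tab <- all_subsets_r2(d, "y", paste0("x", 1:3))
  for (i in seq_len(nrow(tab))) {
    vars <- strsplit(tab$predictors[i], ",")[[1]]
    vars <- vars[nzchar(vars)]
    expect_equal(tab$r2[i], r2_refit(d, "y", vars), tolerance = 1e-10)
  }
})

test_that("subset weighting equals the all-orderings Shapley average", {
  d <- random_design(200, 4, seed = 83)
  preds <- paste0("x", 1:4)
  hp <- hier_partition(d, "y", preds)
  oracle_tbl <- subsets_r2_refit(d, "y", preds)
  by_orders <- shapley_by_orderings(oracle_tbl, preds)
  expect_equal(hp$result$independent, unname(by_orders[preds]),
               tolerance = 1e-10)
})

test_that("subset weighting equals hierarchy-level averaging", {
  d <- random_design(150, 5, seed = 84)
  preds <- paste0("x", 1:5)
  hp <- hier_partition(d, "y", preds)
  oracle_tbl <- subsets_r2_refit(d, "y", preds)
  by_levels <- shapley_by_levels(oracle_tbl, preds)
  expect_equal(hp$result$independent, unname(by_levels[preds]),
               tolerance = 1e-10)
})

test_that("independent contributions conserve the full-model R2", {
  for (k in 1:8) {
    d <- random_design(100, k, seed = 85 + k)
    hp <- hier_partition(d, "y", paste0("x", 1:k))
    expect_equal(sum(hp$result$independent), hp$r_squared,
                 tolerance = 1e-9)
    expect_equal(sum(hp$result$i_pct_r2), 100, tolerance = 1e-6)
    # I_j + J_j is the univariate R2
    uni <- vapply(paste0("x", 1:k), function(v) r2_refit(d, "y", v),
                  numeric(1))
    expect_equal(hp$result$independent + hp$result$joint, unname(uni),
                 tolerance = 1e-9)
  }
})

test_that("a single predictor owns its full univariate R2", {
  d <- random_design(80, 1, seed = 95)
  hp <- hier_partition(d, "y", "x1")
  expect_equal(hp$result$independent, hp$r_squared)
  expect_equal(hp$result$joint, 0)
})

test_that("the decomposition is invariant to predictor order", {
  d <- random_design(120, 5, seed = 96)
  preds <- paste0("x", 1:5)
  a <- hier_partition(d, "y", preds)
  b <- hier_partition(d, "y", rev(preds))
  expect_equal(a$result$independent,
               b$result$independent[match(preds, b$result$predictor)],
               tolerance = 1e-12)
})

test_that("repeated-order runs equal the single run and ignore the seed", {
  d <- random_design(200, 10, seed = 97)
  preds <- paste0("x", 1:10)
  single <- hier_partition(d, "y", preds)
  rep1 <- hier_partition_repeats(d, "y", preds, repeats = 10, seed = 1)
  rep2 <- hier_partition_repeats(d, "y", preds, repeats = 10, seed = 999)
  expect_equal(rep1$result$independent, single$result$independent,
               tolerance = 1e-9)
  expect_equal(rep1$result$independent, rep2$result$independent,
               tolerance = 1e-12)
  expect_equal(rep1$repeats, 10)
})

test_that("predictor budget and sample-size guards hold", {
  d <- random_design(30, 2, seed = 98)
  expect_error(hier_partition(d, "y", rep(paste0("x", 1:2), 7)[1:13]),
               class = "hrvpart_budget_error")
  tiny <- random_design(4, 2, seed = 99)
  expect_error(hier_partition(tiny, "y", c("x1", "x2")),
               class = "hrvpart_length_error")
})

test_that("a duplicated column triggers the pseudoinverse warning path", {
  d <- random_design(50, 2, seed = 100)
  d$x3 <- d$x1
  w <- testthat::capture_warnings(
    hp <- hier_partition(d, "y", c("x1", "x2", "x3")))
  expect_true(any(grepl("pseudoinverse", w)))
  expect_equal(sum(hp$result$independent), hp$r_squared, tolerance = 1e-6)
})

test_that("cohort partitioning reports the valve row and combined R2", {
  sim <- simulate_cohort(cohort_params(n_per_group = c(100, 330, 140)),
                         seed = 30)
  preds <- c("ava", "age", "sbp", "delta_mean_nn")
  row <- partition_cohort(sim$cohort, "delta_alpha1", preds)
  expect_equal(row$valve_parameter, "ava")
  hp <- hier_partition(sim$cohort, "delta_alpha1", preds)
  full <- hp$subsets$r2[hp$subsets$subset == 2^4 - 1]
  expect_equal(row$r_squared, full)
  expect_equal(row$covariables, "age, sbp, delta_mean_nn")
  # no valve parameter among predictors
  row2 <- partition_cohort(sim$cohort, "delta_rmssd",
                           c("age", "delta_mean_nn"))
  expect_true(is.na(row2$valve_parameter))
})

test_that("null valve effect leaves the valve below the top covariable", {
  for (s in 1:3) {
    sim <- simulate_cohort(cohort_params(n_per_group = c(350, 1150, 500),
                                         valve_effect = 0), seed = 200 + s)
    eff <- default_effect_models()$delta_alpha1
    preds <- c("ava", names(eff$covars))
    hp <- hier_partition(sim$cohort, "delta_alpha1", preds)
    i_ava <- hp$result$independent[hp$result$predictor == "ava"]
    expect_lt(i_ava, max(hp$result$independent[hp$result$predictor != "ava"]))
  }
})
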