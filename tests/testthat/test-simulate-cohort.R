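test_that("default cohort reproduces the study group sizes", {
  sim <- simulate_cohort(seed = 1)
  counts <- table(sim$cohort$group)
  expect_equal(as.integer(counts), c(22, 73, 32))
  expect_equal(names(counts), c("NAV", "AVSc", "AVSt"))
  expect_equal(nrow(sim$cohort), 127)
})

test_that("valve severity is ordered across groups", {
  sim <- simulate_cohort(cohort_params(n_per_group = c(100, 300, 150)),
                         seed = 2)
  by_group <- dplyr::summarise(
    sim$cohort,
    ava = mean(ava), pg_mean = mean(pg_mean), pg_max = mean(pg_max),
    vmax = mean(vmax), .by = group)
  by_group <- by_group[match(c("NAV", "AVSc", "AVSt"), by_group$group), ]
  expect_true(all(diff(by_group$ava) < 0))
  expect_true(all(diff(by_group$pg_mean) > 0))
  expect_true(all(diff(by_group$pg_max) > 0))
  expect_true(all(diff(by_group$vmax) > 0))
})

test_that("derived echo quantities satisfy their identities", {
  sim <- simulate_cohort(seed = 3)
  expect_equal(sim$cohort$avai * sim$cohort$bsa, sim$cohort$ava,
               tolerance = 1e-12)
  expect_true(all(sim$cohort$pg_max > sim$cohort$pg_mean))
})

test_that("cohort generation is seed-deterministic", {
  a <- simulate_cohort(seed = 4)$cohort
  b <- simulate_cohort(seed = 4)$cohort
  expect_identical(a, b)
})

test_that("missingness applies to covariates at the requested rate", {
  sim <- simulate_cohort(cohort_params(n_per_group = c(200, 600, 300),
                                       missing_rate = 0.1), seed = 5)
  covars <- setdiff(names(sim$cohort),
                    c("subject_id", "group",
                      grep("^delta_", names(sim$cohort), value = TRUE)))
  rate <- mean(is.na(as.matrix(sim$cohort[covars])))
  expect_lt(abs(rate - 0.1), 0.01)
  deltas <- grep("^delta_", names(sim$cohort), value = TRUE)
  deltas <- setdiff(deltas, "delta_mean_nn")
  expect_false(anyNA(sim$cohort[deltas]))
  expect_error(cohort_params(missing_rate = 1),
               class = "hrvpart_parameter_error")
})

test_that("null-effect cohorts shrink the valve contribution with n", {
  eff <- default_effect_models()$delta_alpha1
  preds <- c("ava", names(eff$covars))
  i_at_n <- vapply(c(100, 500, 2000), function(n) {
    np <- pmax(1, round(c(NAV = 22, AVSc = 73, AVSt = 32) / 127 * n))
    sim <- simulate_cohort(cohort_params(n_per_group = np, valve_effect = 0,
                                         covariate_effect = 0), seed = 6)
    hp <- hier_partition(sim$cohort, "delta_alpha1", preds)
    hp$result$independent[hp$result$predictor == "ava"]
  }, numeric(1))
  expect_lt(i_at_n[3], i_at_n[1])
  expect_lt(i_at_n[3], 0.01)  # below 1% of variance at n = 2000
})

test_that("ground truth records the effect models actually applied", {
  sim <- simulate_cohort(cohort_params(valve_effect = 0.5), seed = 7)
  expect_equal(sim$truth$effects$delta_alpha1$valve_beta,
               default_effect_models()$delta_alpha1$valve_beta * 0.5)
  expect_true(all(c("effects", "reference", "n_per_group") %in%
                    names(sim$truth)))
})

test_that("population partition recovers the calibrated valve target", {
  hp <- population_partition(n = 2e4, seed = 8)
  i_ava <- hp$result$i_pct_abs[hp$result$predictor == "ava"]
  expect_equal(i_ava, 4.6, tolerance = 0.2)
  expect_equal(hp$r_squared, 0.25, tolerance = 0.05)
})

test_that("study simulation couples RR recordings to the cohort", {
  study <- simulate_study(cohort_params(n_per_group = c(4, 5, 4)), seed = 9)
  expect_equal(nrow(study$cohort), 13)
  expect_equal(nrow(study$rr), 13 * 2 * 300)
  expect_setequal(unique(as.character(study$rr$posture)),
                  c("supine", "standing"))
  expect_identical(study$rr, simulate_study(
    cohort_params(n_per_group = c(4, 5, 4)), seed = 9)$rr)
})
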