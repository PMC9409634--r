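test_that("degenerate generator settings give an exactly constant series", {
  rr <- simulate_rr(rr_params(mean_nn = 800, amp_lf = 0, amp_hf = 0,
                              noise_sd = 0))
  expect_equal(rr$interval_ms, rep(800, 300))
  expect_equal(rr$time_s, cumsum(rep(0.8, 300)))
})

test_that("identical parameters and seed reproduce the series bit for bit", {
  a <- simulate_rr(rr_params(), seed = 42)
  b <- simulate_rr(rr_params(), seed = 42)
  expect_identical(a, b)
  c <- simulate_rr(rr_params(), seed = 43)
  expect_false(identical(a$interval_ms, c$interval_ms))
})

test_that("generator parameters are validated", {
  expect_error(rr_params(n_beats = 50), class = "hrvpart_parameter_error")
  expect_error(rr_params(mean_nn = -1), class = "hrvpart_parameter_error")
  expect_error(rr_params(f_lf = 0.2), class = "hrvpart_parameter_error")
  expect_error(rr_params(f_hf = 0.15), class = "hrvpart_parameter_error")
  expect_error(rr_params(fractal_alpha = 0.2),
               class = "hrvpart_parameter_error")
})

test_that("posture pair with pure mean shift yields an exact 0.2 s delta", {
  pair <- simulate_posture_pair(
    rr_params(mean_nn = 1000, amp_lf = 0, amp_hf = 0, noise_sd = 0),
    posture_shift(d_mean_nn = 200, hf_scale = 1, lf_scale = 1,
                  alpha_shift = 0))
  sup <- pair$interval_ms[pair$posture == "supine"]
  sta <- pair$interval_ms[pair$posture == "standing"]
  expect_equal(mean(sup) - mean(sta), 200)
  expect_equal((mean(sup) - mean(sta)) / 1000, 0.2)
})

test_that("a shift exceeding the mean interval is rejected", {
  expect_error(
    simulate_posture_pair(rr_params(mean_nn = 800),
                          posture_shift(d_mean_nn = 900)),
    class = "hrvpart_parameter_error")
})

test_that("null shift draws supine and standing from the same law", {
  shift0 <- posture_shift(d_mean_nn = 0, hf_scale = 1, lf_scale = 1,
                          alpha_shift = 0)
  set.seed(9)
  deltas <- replicate(40, {
    pair <- simulate_posture_pair(rr_params(), shift0)
    mean(pair$interval_ms[pair$posture == "supine"]) -
      mean(pair$interval_ms[pair$posture == "standing"])
  })
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)) + 1)
})

test_that("vagal withdrawal shift flips the normalized-unit balance", {
  # damped HF + amplified LF on standing must push HFn down while standing
  set.seed(31)
  hits <- replicate(30, {
    pair <- simulate_posture_pair(
      rr_params(), posture_shift(d_mean_nn = 200, hf_scale = 0.3,
                                 lf_scale = 1.5, alpha_shift = 0))
    idx <- hrv_compute(pair)
    idx$subject_id <- "s"
    d <- hrv_delta(idx)
    d$delta_hfn > 0 && d$delta_lfn < 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("synthetic ECG places R waves at the cumulative beat times", {
  ecg <- simulate_ecg(rep(800, 10), fs = 250)
  beats <- detect_qrs(ecg, fs = 250)
  expect_equal(unique(diff(beats$index)), 200)
})

test_that("respiration generator validates duration and frequency", {
  expect_error(simulate_resp(duration_s = 0),
               class = "hrvpart_parameter_error")
  expect_error(simulate_resp(f_breath = 13, fs = 25),
               class = "hrvpart_parameter_error")
  r <- simulate_resp(f_breath = 0.27, duration_s = 120, noise_sd = 0)
  expect_equal(nrow(r), 120 * 25 + 1)
})
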