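test_that("a pure LF sinusoid concentrates nearly all band power in LF", {
  rr <- simulate_rr(rr_params(amp_lf = 50, amp_hf = 0, noise_sd = 0))
  sp <- hrv_spectral(rr$interval_ms)
  expect_gte(sp$lfn, 95)
  expect_gte(sp$lf_hf, 19)
})

test_that("a pure HF sinusoid concentrates nearly all band power in HF", {
  rr <- simulate_rr(rr_params(amp_lf = 0, amp_hf = 50, noise_sd = 0))
  sp <- hrv_spectral(rr$interval_ms)
  expect_gte(sp$hfn, 95)
})

test_that("normalized units always sum to exactly 100", {
  set.seed(14)
  for (i in 1:5) {
    rr <- simulate_rr(rr_params(noise_sd = 40))
    sp <- hrv_spectral(rr$interval_ms)
    expect_equal(sp$lfn + sp$hfn, 100, tolerance = 1e-9)
  }
})

test_that("zero band power flags the normalized units as undefined", {
  sp <- hrv_spectral(rep(800, 300))
  expect_true(is.na(sp$lfn))
  expect_true(is.na(sp$hfn))
  expect_true(is.na(sp$lf_hf))
})

test_that("records shorter than 64 s are rejected", {
  expect_error(hrv_spectral(rep(800, 70)), class = "hrvpart_length_error")
})

test_that("PSD is non-negative and the grid spans the Nyquist range", {
  rr <- simulate_rr(rr_params(noise_sd = 30), seed = 3)
  sp <- hrv_spectral(rr$interval_ms)
  spectrum <- attr(sp, "spectrum")
  expect_true(all(spectrum$psd >= 0))
  expect_equal(min(spectrum$freq), 0)
  expect_equal(max(spectrum$freq), 1.5)
})

test_that("band powers agree with an independent periodogram estimate", {
  # deterministic two-tone tachograms; raw periodogram via spec.pgram as the
  # independent method, 5% agreement on the LF/HF balance
  for (amps in list(c(40, 20), c(15, 45), c(30, 30))) {
    rr <- simulate_rr(rr_params(n_beats = 512, amp_lf = amps[1],
                                amp_hf = amps[2], noise_sd = 0))
    sp <- hrv_spectral(rr$interval_ms)
    tach <- resample_tachogram(rr$interval_ms, rate = 3)
    pg <- stats::spec.pgram(stats::ts(tach$rr_ms - mean(tach$rr_ms),
                                      frequency = 3),
                            taper = 0, detrend = TRUE, plot = FALSE)
    lf_ref <- sum(pg$spec[pg$freq >= 0.04 & pg$freq < 0.15])
    hf_ref <- sum(pg$spec[pg$freq >= 0.15 & pg$freq <= 0.4])
    lfn_ref <- 100 * lf_ref / (lf_ref + hf_ref)
    expect_equal(sp$lfn, lfn_ref, tolerance = 0.05)
  }
})

test_that("scale equivariance: intervals in c x ms scale powers by c^2", {
  # rescaling the intervals also dilates the beat times, which shifts the
  # spectral content relative to the fixed band edges; total band power
  # must still follow c^2 closely and the LF/HF balance stay put
  rr <- simulate_rr(rr_params(noise_sd = 30), seed = 5)
  a <- hrv_spectral(rr$interval_ms)
  b <- hrv_spectral(1.05 * rr$interval_ms)
  expect_equal((b$lf + b$hf) / (a$lf + a$hf), 1.05^2, tolerance = 0.05)
  expect_lt(abs(b$lfn - a$lfn), 3)
})

test_that("band-mean convention reports mean PSD instead of integrals", {
  rr <- simulate_rr(rr_params(noise_sd = 30), seed = 6)
  sp_int <- hrv_spectral(rr$interval_ms)
  sp_mean <- hrv_spectral(rr$interval_ms, band_mean = TRUE)
  spectrum <- attr(sp_int, "spectrum")
  lf_mask <- spectrum$freq >= 0.04 & spectrum$freq < 0.15
  expect_equal(sp_mean$lf, mean(spectrum$psd[lf_mask]), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sp_int$lf, sp_mean$lf)))
})
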