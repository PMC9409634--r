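#' Time-domain HRV indices
#'
#' Computes meanNN, SDNN (sample SD, n - 1 denominator), RMSSD (root mean
#' square of successive differences) and pNN20 (percentage of successive
#' differences strictly greater than 20 ms in absolute value).
#'
#' @param intervals Numeric vector of NN intervals in ms (length >= 2).
#'
#' @return A one-row tibble with columns `mean_nn`, `sdnn`, `rmssd`, `pnn20`.
#' @export
#' @examples
#' hrv_time_domain(rep(c(800, 850), 150))
hrv_time_domain <- function(intervals) {
  assert_intervals(intervals, min_length = 2L)
  d <- diff(intervals)
  tibble(
    mean_nn = mean(intervals),
    sdnn = sd(intervals),
    rmssd = sqrt(mean(d^2)),
    pnn20 = 100 * mean(abs(d) > 20)
  )
}

#' Resample an NN tachogram on a uniform time grid
#'
#' Each interval is located at its cumulative end-time and the resulting
#' irregular series is linearly interpolated on a uniform grid at `rate`
#' samples per second, spanning the first to the last beat time. This evenly
#' sampled tachogram is the input to the Welch spectral estimate.
#'
#' @inheritParams hrv_time_domain
#' @param rate Resampling rate in Hz (default 3).
#'
#' @return A tibble with columns `time_s` and `rr_ms`.
#' @export
resample_tachogram <- function(intervals, rate = 3) {
  assert_intervals(intervals, min_length = 2L)
  assert_number(rate, "rate", lower = 1e-9)
  t_beat <- cumsum(intervals) / 1000
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / rate)
  rr <- approx(t_beat, intervals, xout = grid, method = "linear")$y
  tibble(time_s = grid, rr_ms = rr)
}
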