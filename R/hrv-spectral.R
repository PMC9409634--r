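# Welch power spectral density with Hann-windowed overlapping segments.
# One-sided scaling: psd = 2 |X|^2 / (fs * sum(w^2)) except at DC/Nyquist.
welch_psd <- function(x, fs, seg_len = 256, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)) # Hann
  norm <- fs * sum(w^2)
  n_freq <- floor(seg_len / 2) + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- abs(fft(seg)[seq_len(n_freq)])^2
    acc <- acc + spec
  }
  psd <- acc / (length(starts) * norm)
  one_sided <- rep(2, n_freq)
  one_sided[1] <- 1
  if (seg_len %% 2 == 0) one_sided[n_freq] <- 1
  tibble(freq = (seq_len(n_freq) - 1L) * fs / seg_len,
         psd = psd * one_sided)
}

# Integrated (or mean) power over [lo, hi); `closed` includes the upper edge.
band_power <- function(spectrum, lo, hi, closed = FALSE, band_mean = FALSE) {
  keep <- spectrum$freq >= lo &
    (if (closed) spectrum$freq <= hi else spectrum$freq < hi)
  if (sum(keep) < 2) return(0)
  if (band_mean) mean(spectrum$psd[keep])
  else pracma::trapz(spectrum$freq[keep], spectrum$psd[keep])
}

#' Frequency-domain HRV indices
#'
#' Resamples the tachogram at `rate` Hz ([resample_tachogram()]), removes the
#' mean, estimates the power spectral density with Welch's method
#' (Hann-windowed segments of `seg_len` samples with proportion `overlap`
#' overlap, per-segment mean removal), and integrates the PSD over the LF
#' band \[0.04, 0.15) Hz and the HF band \[0.15, 0.4\] Hz. Normalized units
#' are each band's share of LF + HF on a 0--100 scale, so `lfn + hfn = 100`
#' whenever LF + HF > 0.
#'
#' @inheritParams resample_tachogram
#' @param seg_len Welch segment length in samples (default 256, ~85 s at
#'   3 Hz).
#' @param overlap Segment overlap fraction (default 0.5).
#' @param lf_band,hf_band Band limits in Hz. The LF band is half-open on the
#'   right; the HF band includes its upper edge.
#' @param band_mean If `TRUE` report the mean PSD over each band instead of
#'   the trapezoid-integrated band power (ms^2); the integrated convention is
#'   the default.
#'
#' @return A one-row tibble with columns `lf`, `hf` (ms^2), `lfn`, `hfn`
#'   (normalized units), `lf_hf`, carrying the PSD as attribute `spectrum`
#'   (a tibble of class `hrv_spectrum` with `freq`, `psd`). `lfn`/`hfn` are
#'   `NA` when LF + HF = 0 and `lf_hf` is `NA` when HF = 0.
#' @export
#' @examples
#' rr <- simulate_rr(rr_params(amp_lf = 50, amp_hf = 0, noise_sd = 0))
#' hrv_spectral(rr$interval_ms)
hrv_spectral <- function(intervals, rate = 3, seg_len = 256, overlap = 0.5,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                         band_mean = FALSE) {
  tach <- resample_tachogram(intervals, rate = rate)
  if (nrow(tach) / rate < 64) {
    abort("Need at least 64 s of resampled tachogram for spectral indices.",
          class = "hrvpart_length_error")
  }
  x <- tach$rr_ms - mean(tach$rr_ms)
  spectrum <- welch_psd(x, fs = rate, seg_len = seg_len, overlap = overlap)
  lf <- band_power(spectrum, lf_band[1], lf_band[2], closed = FALSE,
                   band_mean = band_mean)
  hf <- band_power(spectrum, hf_band[1], hf_band[2], closed = TRUE,
                   band_mean = band_mean)
  tot <- lf + hf
  out <- tibble(
    lf = lf, hf = hf,
    lfn = if (tot > 0) 100 * lf / tot else NA_real_,
    hfn = if (tot > 0) 100 * hf / tot else NA_real_,
    lf_hf = if (hf > 0) lf / hf else NA_real_
  )
  spectrum <- structure(spectrum, class = c("hrv_spectrum", class(spectrum)),
                        rate = rate, seg_len = seg_len, overlap = overlap)
  attr(out, "spectrum") <- spectrum
  out
}
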