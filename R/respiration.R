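#' Mean breathing frequency from a respiration waveform
#'
#' Computes the magnitude spectrum of the mean-removed signal with a single
#' whole-record discrete Fourier transform and reports the frequency of
#' maximum power within the search band (default 0.05--1.0 Hz, which
#' excludes DC and slow drift while covering the physiological breathing
#' range).
#'
#' @param resp A numeric vector of samples, or a data frame with columns
#'   `time_s` and `resp` (as from [simulate_resp()]).
#' @param fs Sampling rate in Hz (default 25); inferred from `time_s` when
#'   `resp` is a data frame.
#' @param band Search band in Hz.
#'
#' @return A one-row tibble with columns `mbf_hz`, `peak_power`,
#'   `resolution_hz` (the DFT bin width fs/N), `band_lo`, `band_hi`. The
#'   power spectrum is attached as attribute `spectrum`. `mbf_hz` is `NA`
#'   for an all-zero signal.
#' @export
#' @examples
#' mbf(simulate_resp(f_breath = 0.27, duration_s = 120))
mbf <- function(resp, fs = 25, band = c(0.05, 1.0)) {
  if (is.data.frame(resp)) {
    fs <- 1 / median(diff(resp$time_s))
    resp <- resp$resp
  }
  assert_number(fs, "fs", lower = 1e-9)
  n <- length(resp)
  if (n / fs < 60) {
    abort("Respiration record must be at least 60 s long.",
          class = "hrvpart_length_error")
  }
  x <- resp - mean(resp)
  resolution <- fs / n
  if (all(x == 0)) {
    out <- tibble(mbf_hz = NA_real_, peak_power = 0,
                  resolution_hz = resolution,
                  band_lo = band[1], band_hi = band[2])
    attr(out, "undefined") <- "all-zero signal"
    return(out)
  }
  power <- abs(fft(x))^2 / n
  freq <- (seq_len(n) - 1L) * resolution
  keep <- freq >= band[1] & freq <= min(band[2], fs / 2)
  spectrum <- tibble(freq = freq[keep], power = power[keep])
  peak <- which.max(spectrum$power)
  out <- tibble(mbf_hz = spectrum$freq[peak],
                peak_power = spectrum$power[peak],
                resolution_hz = resolution,
                band_lo = band[1], band_hi = band[2])
  attr(out, "spectrum") <- spectrum
  out
}
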