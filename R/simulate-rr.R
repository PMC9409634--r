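#' Parameters for synthetic RR-interval series
#'
#' Bundles the generator settings for [simulate_rr()]: a mean interval, low-
#' and high-frequency sinusoidal modulations (the spectral signatures of
#' sympathetic/vagal rhythms), and a fractal noise floor whose short-term
#' detrended-fluctuation exponent is set by `fractal_alpha`.
#'
#' @param n_beats Number of beats to generate (>= 64; default 300, the
#'   segment length used throughout the package).
#' @param mean_nn Mean NN interval in ms (> 0).
#' @param amp_lf,amp_hf Amplitudes (ms) of the sinusoidal modulations at
#'   `f_lf` and `f_hf`.
#' @param f_lf Low-frequency modulation frequency in Hz, inside the LF band
#'   (0.04--0.15 Hz).
#' @param f_hf High-frequency modulation frequency in Hz, inside the HF band
#'   (0.15--0.4 Hz].
#' @param fractal_alpha Target DFA scaling exponent of the noise component,
#'   in \[0.5, 1.5\] (0.5 = white noise, 1.0 = 1/f noise).
#' @param noise_sd Standard deviation (ms) of the fractal noise component.
#'
#' @return A validated list of class `"rr_params"`.
#' @seealso [simulate_rr()], [posture_shift()]
#' @export
#' @examples
#' rr_params(mean_nn = 800, amp_lf = 20)
rr_params <- function(n_beats = 300, mean_nn = 900, amp_lf = 30, f_lf = 0.10,
                      amp_hf = 40, f_hf = 0.25, fractal_alpha = 0.9,
                      noise_sd = 20) {
  n_beats <- assert_count(n_beats, "n_beats", lower = 64)
  assert_number(mean_nn, "mean_nn", lower = 1e-9)
  assert_number(amp_lf, "amp_lf", lower = 0)
  assert_number(amp_hf, "amp_hf", lower = 0)
  assert_number(f_lf, "f_lf", lower = 0.04, upper = 0.15)
  assert_number(f_hf, "f_hf", lower = 0.15, upper = 0.4)
  if (f_hf <= 0.15) {
    abort("`f_hf` must be strictly greater than 0.15 Hz.",
          class = "hrvpart_parameter_error")
  }
  assert_number(fractal_alpha, "fractal_alpha", lower = 0.5, upper = 1.5)
  assert_number(noise_sd, "noise_sd", lower = 0)
  structure(list(n_beats = n_beats, mean_nn = mean_nn, amp_lf = amp_lf,
                 f_lf = f_lf, amp_hf = amp_hf, f_hf = f_hf,
                 fractal_alpha = fractal_alpha, noise_sd = noise_sd),
            class = "rr_params")
}

#' Posture shift applied to the RR generator on active standing
#'
#' Describes how generator parameters change from supine rest to active
#' standing: a shorter mean NN interval (faster heart rate), damped HF
#' modulation (vagal withdrawal), amplified LF modulation (sympathetic
#' activation), and an increased scaling exponent. With the defaults the
#' supine-minus-standing deltas reproduce the sign pattern seen in
#' orthostatic-challenge studies: delta meanNN > 0, delta HFn > 0,
#' delta LFn < 0, delta alpha1 < 0.
#'
#' @param d_mean_nn Drop of the mean NN interval on standing, ms (>= 0).
#' @param hf_scale Multiplier on `amp_hf` when standing, in (0, 1].
#' @param lf_scale Multiplier on `amp_lf` when standing (>= 1).
#' @param alpha_shift Additive increase of `fractal_alpha` when standing.
#'
#' @return A validated list of class `"posture_shift"`.
#' @export
posture_shift <- function(d_mean_nn = 200, hf_scale = 0.3, lf_scale = 1.6,
                          alpha_shift = 0.35) {
  assert_number(d_mean_nn, "d_mean_nn", lower = 0)
  assert_number(hf_scale, "hf_scale", lower = 1e-12, upper = 1)
  assert_number(lf_scale, "lf_scale", lower = 1)
  assert_number(alpha_shift, "alpha_shift")
  structure(list(d_mean_nn = d_mean_nn, hf_scale = hf_scale,
                 lf_scale = lf_scale, alpha_shift = alpha_shift),
            class = "posture_shift")
}

# DFA-calibrated mapping from a target short-range scaling exponent to the
# power-spectrum exponent used by the surrogate. Asymptotically
# beta = 2*alpha - 1, but order-1 DFA restricted to box sizes 4-11 has a
# finite-size bias (true white noise, beta = 0, has expected slope 0.617
# there, not 0.5). The map below was solved from the exact expectation of
# the detrended fluctuation under the synthesis spectrum, so the generated
# noise measures alpha on the same scale range the estimator uses.
alpha_to_beta <- function(alpha) {
  approx(x = seq(0.4, 1.6, by = 0.1),
         y = c(-0.7163, -0.3547, -0.0492, 0.2208, 0.4664, 0.6947, 0.9100,
               1.1154, 1.3132, 1.5050, 1.6920, 1.8752, 2.0555),
         xout = alpha, rule = 2)$y
}

# Fractal noise by inverse-spectral shaping: random phases, amplitude
# proportional to f^(-beta/2), beta chosen so the series' short-range DFA
# exponent matches `alpha`. Returns a zero-mean, unit-SD series of length n.
fractal_noise <- function(n, alpha) {
  beta <- alpha_to_beta(alpha)
  n_half <- floor(n / 2)
  freq <- seq_len(n_half) / n
  amp <- freq^(-beta / 2)
  phase <- runif(n_half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(n_half + 1)] <- spec
  # Hermitian symmetry so the inverse transform is real
  if (n %% 2 == 0) {
    full[n_half + 1] <- complex(real = amp[n_half] * cos(phase[n_half]))
    if (n_half > 1) full[(n_half + 2):n] <- Conj(spec[(n_half - 1):1])
  } else {
    full[(n_half + 2):n] <- Conj(spec[n_half:1])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate an NN-interval series
#'
#' Generates `n_beats` RR intervals as `mean_nn` plus LF and HF sinusoids
#' evaluated at the cumulative beat times, plus fractal noise synthesized by
#' inverse-spectral shaping calibrated so its DFA exponent matches
#' `fractal_alpha`.
#'
#' @param params An [rr_params()] object.
#' @param seed Optional integer seed. `NULL` (default) draws from the current
#'   RNG stream, which lets callers generate several series reproducibly
#'   under one outer seed.
#'
#' @return A tibble with columns `beat`, `time_s` (cumulative end-time of
#'   each interval) and `interval_ms`.
#' @export
#' @examples
#' rr <- simulate_rr(rr_params(mean_nn = 800), seed = 1)
#' head(rr)
simulate_rr <- function(params = rr_params(), seed = NULL) {
  stopifnot(inherits(params, "rr_params"))
  with_seed(seed, {
    n <- params$n_beats
    noise <- if (params$noise_sd > 0) {
      params$noise_sd * fractal_noise(n, params$fractal_alpha)
    } else {
      numeric(n)
    }
    intervals <- numeric(n)
    t_prev <- 0
    for (k in seq_len(n)) {
      intervals[k] <- params$mean_nn +
        params$amp_lf * sin(2 * pi * params$f_lf * t_prev) +
        params$amp_hf * sin(2 * pi * params$f_hf * t_prev) +
        noise[k]
      t_prev <- t_prev + intervals[k] / 1000
    }
    if (any(intervals <= 0)) {
      abort("Generator parameters produced non-positive intervals; reduce amplitudes or noise_sd.",
            class = "hrvpart_parameter_error")
    }
    tibble(beat = seq_len(n), time_s = cumsum(intervals) / 1000,
           interval_ms = intervals)
  })
}

#' Simulate a supine/standing pair of NN series
#'
#' Draws a supine series from `params` and a standing series from the shifted
#' parameters given by `shift` (see [posture_shift()]); the two draws are
#' independent.
#'
#' @inheritParams simulate_rr
#' @param shift A [posture_shift()] object.
#'
#' @return A tibble with columns `posture` (factor, levels supine/standing),
#'   `beat`, `time_s`, `interval_ms`.
#' @export
simulate_posture_pair <- function(params = rr_params(),
                                  shift = posture_shift(), seed = NULL) {
  stopifnot(inherits(params, "rr_params"), inherits(shift, "posture_shift"))
  standing_mean <- params$mean_nn - shift$d_mean_nn
  if (standing_mean <= 0) {
    abort("`d_mean_nn` leaves a non-positive standing mean NN interval.",
          class = "hrvpart_parameter_error")
  }
  standing_alpha <- min(max(params$fractal_alpha + shift$alpha_shift, 0.5), 1.5)
  standing <- rr_params(
    n_beats = params$n_beats, mean_nn = standing_mean,
    amp_lf = params$amp_lf * shift$lf_scale, f_lf = params$f_lf,
    amp_hf = params$amp_hf * shift$hf_scale, f_hf = params$f_hf,
    fractal_alpha = standing_alpha, noise_sd = params$noise_sd
  )
  with_seed(seed, {
    sup <- simulate_rr(params)
    sta <- simulate_rr(standing)
    dplyr::bind_rows(
      dplyr::mutate(sup, posture = "supine", .before = 1),
      dplyr::mutate(sta, posture = "standing", .before = 1)
    ) |>
      dplyr::mutate(posture = factor(.data$posture,
                                     levels = c("supine", "standing")))
  })
}

#' Simulate a single-lead ECG from an RR series
#'
#' Places one Gaussian-shaped R wave at each cumulative beat time (including
#' a beat at time zero, so successive R-peak differences recover every input
#' interval), with optional sinusoidal baseline wander and white measurement
#' noise. Intended as a test input for the QRS detector, not as a
#' morphologically realistic ECG.
#'
#' @param intervals_ms Numeric vector of RR intervals in ms.
#' @param fs Sampling rate in Hz (>= 100).
#' @param r_amp R-wave amplitude (arbitrary units).
#' @param r_sd_ms Gaussian R-wave width (standard deviation) in ms.
#' @param baseline_amp,baseline_freq Amplitude and frequency of optional
#'   sinusoidal baseline wander.
#' @param noise_sd SD of additive white noise.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#'
#' @return A tibble with columns `time_s` and `ecg`.
#' @export
simulate_ecg <- function(intervals_ms, fs = 250, r_amp = 1, r_sd_ms = 10,
                         baseline_amp = 0, baseline_freq = 0.2,
                         noise_sd = 0, seed = NULL) {
  assert_intervals(intervals_ms, "intervals_ms")
  assert_number(fs, "fs", lower = 100)
  assert_number(noise_sd, "noise_sd", lower = 0)
  # 0.3 s lead-in so the first R wave is fully inside the record
  beat_times <- c(0, cumsum(intervals_ms)) / 1000 + 0.3
  duration <- max(beat_times) + 0.3
  t <- seq(0, duration, by = 1 / fs)
  ecg <- numeric(length(t))
  sd_s <- r_sd_ms / 1000
  half <- 5 * sd_s
  for (bt in beat_times) {
    idx <- which(t >= bt - half & t <= bt + half)
    ecg[idx] <- ecg[idx] + r_amp * exp(-((t[idx] - bt)^2) / (2 * sd_s^2))
  }
  if (baseline_amp > 0) {
    ecg <- ecg + baseline_amp * sin(2 * pi * baseline_freq * t)
  }
  with_seed(seed, {
    if (noise_sd > 0) ecg <- ecg + rnorm(length(t), sd = noise_sd)
    tibble(time_s = t, ecg = ecg)
  })
}

#' Simulate a respiration waveform
#'
#' A sinusoid at the breathing frequency plus optional white noise, sampled
#' at `fs` (chest-band respiration channels are typically sampled at 25 Hz).
#'
#' @param f_breath Breathing frequency in Hz, in (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds (> 0).
#' @param amp Sinusoid amplitude.
#' @param noise_sd SD of additive white noise.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time_s` and `resp`.
#' @export
simulate_resp <- function(f_breath = 0.27, fs = 25, duration_s = 300,
                          amp = 1, noise_sd = 0, seed = NULL) {
  assert_number(fs, "fs", lower = 1e-9)
  assert_number(f_breath, "f_breath", lower = 1e-9)
  if (f_breath >= fs / 2) {
    abort("`f_breath` must be below the Nyquist frequency fs/2.",
          class = "hrvpart_parameter_error")
  }
  assert_number(duration_s, "duration_s", lower = 1e-9)
  assert_number(noise_sd, "noise_sd", lower = 0)
  t <- seq(0, duration_s, by = 1 / fs)
  with_seed(seed, {
    x <- amp * sin(2 * pi * f_breath * t)
    if (noise_sd > 0) x <- x + rnorm(length(t), sd = noise_sd)
    tibble(time_s = t, resp = x)
  })
}
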