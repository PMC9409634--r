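#' Detect QRS complexes in a single-lead ECG
#'
#' Second-derivative detector: moving-average smoothing, discrete second
#' derivative, squared magnitude, an adaptive threshold (a fraction of the
#' running maximum over a sliding window), and refractory-period
#' suppression. Candidate positions are refined to the local maximum of the
#' smoothed signal.
#'
#' @param ecg A numeric vector of samples, or a data frame with columns
#'   `time_s` and `ecg` (as produced by [simulate_ecg()]).
#' @param fs Sampling rate in Hz (>= 100); inferred from `time_s` when `ecg`
#'   is a data frame.
#' @param smooth_ms Moving-average window, ms.
#' @param threshold_frac Threshold as a fraction of the running maximum of
#'   the squared second derivative.
#' @param window_s Running-maximum window, seconds.
#' @param refractory_ms Minimum spacing between detections, ms.
#'
#' @return A tibble with columns `beat`, `index` (1-based sample index) and
#'   `time_s`. Zero rows, with a warning, if no beats are found.
#' @seealso [beats_to_rr()]
#' @export
#' @examples
#' ecg <- simulate_ecg(rep(800, 20))
#' detect_qrs(ecg)
detect_qrs <- function(ecg, fs = NULL, smooth_ms = 40, threshold_frac = 0.4,
                       window_s = 2, refractory_ms = 200) {
  if (is.data.frame(ecg)) {
    if (is.null(fs)) fs <- 1 / median(diff(ecg$time_s))
    ecg <- ecg$ecg
  }
  assert_number(fs, "fs", lower = 100)
  if (length(ecg) < 2 * fs) {
    abort("ECG must be at least 2 s long.", class = "hrvpart_length_error")
  }
  k <- max(3L, as.integer(round(fs * smooth_ms / 1000)))
  if (k %% 2 == 0) k <- k + 1L
  x <- as.numeric(stats::filter(ecg, rep(1 / k, k), sides = 2))
  # pad the filter edges with the nearest smoothed value so the second
  # derivative sees no artificial discontinuity at the record boundaries
  valid <- which(!is.na(x))
  x[seq_len(valid[1] - 1)] <- x[valid[1]]
  x[seq((valid[length(valid)] + 1), length.out = length(x) - valid[length(valid)])] <-
    x[valid[length(valid)]]
  # second derivative on a stencil matched to the QRS width (20 ms spacing)
  # so the curvature of the R wave, not sample-to-sample noise, drives the
  # feature
  h <- max(1L, as.integer(round(fs * 0.02)))
  n <- length(x)
  feature <- numeric(n)
  idx2 <- (h + 1L):(n - h)
  feature[idx2] <- (x[idx2 + h] - 2 * x[idx2] + x[idx2 - h])^2
  feature[c(seq_len(k + h), n - seq_len(k + h) + 1L)] <- 0  # edge guard
  win <- max(3L, as.integer(round(fs * window_s)))
  runmax <- running_max(feature, win)
  above <- runmax > 0 & feature >= threshold_frac * runmax
  if (!any(above)) {
    warn("No QRS complexes detected.")
    return(tibble(beat = integer(), index = integer(), time_s = numeric()))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- purrr::map_int(which(runs$values), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(feature[seg])]
  })
  # refractory suppression: within the dead time keep the stronger candidate
  refract <- fs * refractory_ms / 1000
  kept <- cand[1]
  for (ci in cand[-1]) {
    last <- kept[length(kept)]
    if (ci - last > refract) {
      kept <- c(kept, ci)
    } else if (feature[ci] > feature[last]) {
      kept[length(kept)] <- ci
    }
  }
  # refine to the local maximum of the smoothed signal
  half <- as.integer(round(fs * 0.05))
  idx <- purrr::map_int(kept, function(ci) {
    lo <- max(1L, ci - half)
    hi <- min(length(x), ci + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  })
  idx <- unique(idx)
  tibble(beat = seq_along(idx), index = idx, time_s = (idx - 1) / fs)
}

# running maximum over a centered window (plain O(n*w/step) block scan kept
# simple; windows are short relative to the record)
running_max <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  out <- numeric(n)
  # block maxima at stride half, then each sample takes the max of the
  # blocks overlapping its window
  starts <- seq(1L, n, by = max(1L, half))
  blocks <- purrr::map_dbl(starts, function(s) max(x[s:min(n, s + half - 1L)]))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    b <- which(starts <= hi & (starts + half - 1L) >= lo)
    out[i] <- max(blocks[b])
  }
  out
}

#' RR intervals from detected beat indices
#'
#' @param beats Output of [detect_qrs()] (or an integer vector of sample
#'   indices).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of RR intervals in ms.
#' @export
beats_to_rr <- function(beats, fs) {
  if (is.data.frame(beats)) beats <- beats$index
  assert_number(fs, "fs", lower = 1e-9)
  diff(beats) / fs * 1000
}

#' Automated NN cleaning of a raw RR series
#'
#' Removes (never interpolates) intervals outside the absolute limits
#' `[min_ms, max_ms]` or deviating more than `rel_tol` from the median of
#' the previous five accepted intervals -- an automated, reproducible
#' surrogate for manual artifact/ectopy editing. The number of removed
#' intervals is recorded in the `n_removed` attribute.
#'
#' @param intervals Numeric vector of raw RR intervals in ms (length >= 2).
#' @param min_ms,max_ms Absolute physiological limits, ms.
#' @param rel_tol Maximum relative deviation from the running median.
#' @param max_removed_frac Abort (data-quality error) when more than this
#'   fraction of intervals is removed.
#' @param series_id Optional label naming the series in error messages.
#'
#' @return The accepted intervals, with attribute `n_removed`.
#' @export
#' @examples
#' x <- rep(800, 50); x[25] <- 2500
#' clean_rr(x)
clean_rr <- function(intervals, min_ms = 300, max_ms = 2000, rel_tol = 0.2,
                     max_removed_frac = 0.2, series_id = NULL) {
  assert_intervals(intervals, min_length = 2L)
  accepted <- numeric(0)
  for (v in intervals) {
    ok <- v >= min_ms && v <= max_ms
    if (ok && length(accepted) > 0) {
      ref <- median(tail(accepted, 5))
      ok <- abs(v - ref) <= rel_tol * ref
    }
    if (ok) accepted <- c(accepted, v)
  }
  n_removed <- length(intervals) - length(accepted)
  if (n_removed > max_removed_frac * length(intervals)) {
    abort(sprintf("Series %s: %d of %d intervals (%.0f%%) removed by cleaning.",
                  series_id %||% "<unnamed>", n_removed, length(intervals),
                  100 * n_removed / length(intervals)),
          class = "hrvpart_quality_error")
  }
  structure(accepted, n_removed = n_removed)
}

#' Select a contiguous analysis segment
#'
#' Returns `n` contiguous intervals starting after `skip`, the convention
#' used to cut a fixed-length (300-beat) segment out of a longer cleaned
#' recording.
#'
#' @param intervals Cleaned NN intervals, ms.
#' @param n Segment length in beats (default 300).
#' @param skip Number of leading intervals to skip.
#'
#' @return Numeric vector of length `n`.
#' @export
select_segment <- function(intervals, n = 300, skip = 0) {
  n <- assert_count(n, "n", lower = 1L)
  skip <- assert_count(skip, "skip", lower = 0L)
  if (length(intervals) < skip + n) {
    abort(sprintf("Need %d intervals (skip %d + n %d), have %d.",
                  skip + n, skip, n, length(intervals)),
          class = "hrvpart_length_error")
  }
  intervals[(skip + 1):(skip + n)]
}
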