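#' Detrended fluctuation function of an NN series
#'
#' Integrates the mean-subtracted series, partitions the profile into
#' non-overlapping boxes of each `scale` (discarding the remainder), removes
#' a least-squares line per box, and reports the root-mean-square residual
#' over all covered points.
#'
#' @inheritParams hrv_time_domain
#' @param scales Integer box sizes (default 4:11, the short-term range).
#'
#' @return A tibble with columns `scale` and `fluctuation`.
#' @export
dfa_fluctuation <- function(intervals, scales = 4:11) {
  assert_intervals(intervals, min_length = max(scales) + 1L)
  y <- cumsum(intervals - mean(intervals))
  n <- length(y)
  purrr::map_dfr(as.integer(scales), function(s) {
    n_box <- n %/% s
    yy <- matrix(y[seq_len(n_box * s)], nrow = s)
    t <- seq_len(s)
    X <- cbind(1, t)
    # residual-maker applied to every box at once
    res <- yy - X %*% solve(crossprod(X), crossprod(X, yy))
    tibble(scale = s, fluctuation = sqrt(mean(res^2)))
  })
}

#' Short-term DFA scaling exponent alpha1
#'
#' Least-squares slope of log fluctuation versus log box size over box sizes
#' 4--11 beats (natural logs; the slope is base-invariant). Values near 0.5
#' indicate uncorrelated intervals, near 1.0 1/f-like correlations.
#'
#' @inheritParams dfa_fluctuation
#'
#' @return The scaling exponent, or `NA` (with attribute
#'   `undefined = "zero fluctuation"`) for constant input.
#' @export
#' @examples
#' rr <- simulate_rr(rr_params(n_beats = 512, amp_lf = 0, amp_hf = 0,
#'                             fractal_alpha = 0.5), seed = 1)
#' dfa_alpha1(rr$interval_ms)
dfa_alpha1 <- function(intervals, scales = 4:11) {
  assert_intervals(intervals, min_length = 100L)
  fl <- dfa_fluctuation(intervals, scales)
  if (any(fl$fluctuation == 0)) {
    return(structure(NA_real_, undefined = "zero fluctuation"))
  }
  unname(coef(lm(log(fluctuation) ~ log(scale), data = fl))[2])
}

#' Sample entropy
#'
#' SampEn(m, r): the negative natural log of the conditional probability
#' that templates matching for `m` beats (Chebyshev distance <= r,
#' self-matches excluded) also match for `m + 1` beats. The tolerance is
#' `r_factor` times the sample SD unless `r` is given directly, so the index
#' is invariant to rescaling the series.
#'
#' @inheritParams hrv_time_domain
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of the sample SD (default 0.2).
#' @param r Absolute tolerance in ms; overrides `r_factor` when given.
#'
#' @return The entropy value, or `NA` with attributes `undefined`, `A`, `B`
#'   when no template pairs match at length m or m + 1 (e.g. constant
#'   input, where r = 0).
#' @export
sampen <- function(intervals, m = 2, r_factor = 0.2, r = NULL) {
  m <- assert_count(m, "m", lower = 1L)
  assert_intervals(intervals, min_length = m + 2L)
  assert_number(r_factor, "r_factor", lower = 0)
  if (is.null(r)) r <- r_factor * sd(intervals)
  if (r <= 0) {
    # constant input degenerates to r = 0, where every template trivially
    # matches itself; flag rather than report 0
    return(structure(NA_real_, undefined = "no matching templates",
                     A = 0, B = 0))
  }
  x <- as.numeric(intervals)
  n_t <- length(x) - m   # templates usable at both lengths m and m + 1
  a <- 0; b <- 0
  for (i in seq_len(n_t - 1L)) {
    j <- (i + 1L):n_t
    ok <- rep(TRUE, length(j))
    for (k in 0:(m - 1L)) {
      ok <- ok & abs(x[i + k] - x[j + k]) <= r
      if (!any(ok)) break
    }
    if (!any(ok)) next
    b <- b + sum(ok)
    a <- a + sum(ok & abs(x[i + m] - x[j + m]) <= r)
  }
  if (a == 0 || b == 0) {
    return(structure(NA_real_, undefined = "no matching templates",
                     A = a, B = b))
  }
  -log(a / b)
}
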