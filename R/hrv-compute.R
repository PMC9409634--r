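#' All eleven HRV indices for one NN series
#'
#' Convenience wrapper around [hrv_time_domain()], [hrv_spectral()],
#' [dfa_alpha1()] and [sampen()].
#'
#' @inheritParams hrv_spectral
#' @inheritParams dfa_alpha1
#' @inheritParams sampen
#'
#' @return A one-row tibble with columns `mean_nn`, `sdnn`, `rmssd`, `pnn20`,
#'   `lf`, `hf`, `lfn`, `hfn`, `lf_hf`, `alpha1`, `sampen`.
#' @export
#' @examples
#' rr <- simulate_rr(seed = 7)
#' hrv_indices(rr$interval_ms)
hrv_indices <- function(intervals, rate = 3, seg_len = 256, overlap = 0.5,
                        scales = 4:11, m = 2, r_factor = 0.2,
                        band_mean = FALSE) {
  td <- hrv_time_domain(intervals)
  sp <- hrv_spectral(intervals, rate = rate, seg_len = seg_len,
                     overlap = overlap, band_mean = band_mean)
  attr(sp, "spectrum") <- NULL
  dplyr::bind_cols(
    td, sp,
    tibble(alpha1 = as.numeric(dfa_alpha1(intervals, scales)),
           sampen = as.numeric(sampen(intervals, m = m,
                                      r_factor = r_factor)))
  )
}

#' Compute HRV indices for every series in a long table
#'
#' Takes a long table with one row per beat (such as the output of
#' [simulate_posture_pair()] or [read_rr()] bound over subjects) and returns
#' one row of indices per series, where a series is identified by every
#' column other than the interval column and the per-beat bookkeeping
#' columns `beat` and `time_s`.
#'
#' @param df A data frame with one row per beat.
#' @param interval Column holding intervals in ms (default `interval_ms`).
#' @param ... Passed on to [hrv_indices()].
#'
#' @return A tibble with the identifying columns plus the eleven index
#'   columns.
#' @export
#' @examples
#' simulate_posture_pair(seed = 3) |> hrv_compute()
hrv_compute <- function(df, interval = interval_ms, ...) {
  icol <- as_name(enquo(interval))
  if (!icol %in% names(df)) {
    abort(sprintf("Column `%s` not found.", icol),
          class = "hrvpart_parameter_error")
  }
  keys <- setdiff(names(df), c(icol, "beat", "time_s"))
  dplyr::reframe(df, hrv_indices(.data[[icol]], ...),
                 .by = dplyr::all_of(keys))
}

#' Supine-minus-standing deltas of HRV indices
#'
#' Pairs each subject's supine and standing index rows and returns the
#' element-wise difference supine minus standing, the magnitude of the
#' orthostatic response. `delta_mean_nn` is reported in seconds (the field
#' convention); all other deltas keep their index's units. Undefined (`NA`)
#' index values propagate into the delta.
#'
#' @param df Output of [hrv_compute()]: one row per subject and posture.
#' @param subject,posture Columns identifying the subject and the posture;
#'   posture values must be `"supine"` and `"standing"`.
#'
#' @return A tibble with one row per subject: the subject column, any other
#'   identifying columns (taken from the supine row), and `delta_*` columns
#'   for the eleven indices.
#' @export
hrv_delta <- function(df, subject = subject_id, posture = posture) {
  scol <- as_name(enquo(subject))
  pcol <- as_name(enquo(posture))
  idx <- c("mean_nn", "sdnn", "rmssd", "pnn20", "lf", "hf", "lfn", "hfn",
           "lf_hf", "alpha1", "sampen")
  missing_cols <- setdiff(c(scol, pcol, idx), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "hrvpart_parameter_error")
  }
  df <- dplyr::mutate(df, !!pcol := as.character(.data[[pcol]]))
  sup <- dplyr::filter(df, .data[[pcol]] == "supine")
  sta <- dplyr::filter(df, .data[[pcol]] == "standing")
  if (anyDuplicated(sup[[scol]]) || anyDuplicated(sta[[scol]])) {
    abort("Each subject must have exactly one series per posture.",
          class = "hrvpart_identity_error")
  }
  both <- intersect(sup[[scol]], sta[[scol]])
  dropped <- setdiff(unique(df[[scol]]), both)
  if (length(dropped) > 0) {
    warn(paste0("Dropping subjects without both postures: ",
                paste(dropped, collapse = ", ")))
  }
  sup <- sup[match(both, sup[[scol]]), , drop = FALSE]
  sta <- sta[match(both, sta[[scol]]), , drop = FALSE]
  deltas <- purrr::map(idx, function(v) sup[[v]] - sta[[v]])
  names(deltas) <- paste0("delta_", idx)
  deltas$delta_mean_nn <- deltas$delta_mean_nn / 1000  # report in seconds
  extra <- setdiff(names(df), c(scol, pcol, idx))
  dplyr::bind_cols(sup[, c(scol, extra), drop = FALSE], tibble::new_tibble(deltas))
}
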