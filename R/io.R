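#' Read and write plain-text RR series
#'
#' The interchange format is one interval in milliseconds per line; blank
#' lines and lines starting with `#` are ignored. Malformed or non-positive
#' values raise a parse error naming the line.
#'
#' @param path File path.
#' @return `read_rr()` returns a numeric vector of intervals in ms.
#' @export
read_rr <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Invalid RR value at line %d of %s: '%s'",
                  keep[bad[1]], path, lines[keep[bad[1]]]),
          class = "hrvpart_parse_error")
  }
  vals
}

#' @rdname read_rr
#' @param intervals Numeric vector of intervals in ms.
#' @export
write_rr <- function(intervals, path) {
  assert_intervals(intervals)
  readr::write_lines(format(intervals, trim = TRUE, scientific = FALSE),
                     path)
  invisible(path)
}

#' Read and write cohort tables
#'
#' Cohort tables are CSV files with one row per subject; `group` and
#' `subject_id` are the only required columns. Unknown columns are carried
#' through untouched with a warning, so site-specific covariates survive a
#' round trip.
#'
#' @param path File path.
#' @return `read_cohort()` returns a tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hrvpart_parse_error")
  }
  known <- c(required, ref_moments()$variable, "mmp2", "pg_max", "avai",
             "lvmi", "mmp2_timp1",
             paste0("delta_", c("mean_nn", "sdnn", "rmssd", "pnn20", "lf",
                                "hf", "lfn", "hfn", "lf_hf", "alpha1",
                                "sampen")))
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0) {
    warn(paste0("Unknown cohort column(s) carried through: ",
                paste(unknown, collapse = ", ")))
  }
  df
}

#' @rdname read_cohort
#' @param df A cohort data frame.
#' @export
write_cohort <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
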