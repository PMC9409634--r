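# internal argument checks ----------------------------------------------------

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be a single number, not NULL.", name),
          class = "hrvpart_parameter_error")
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "hrvpart_parameter_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)),
          class = "hrvpart_parameter_error")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_number(x, name, lower = lower)
  if (x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "hrvpart_parameter_error")
  }
  invisible(as.integer(x))
}

assert_intervals <- function(x, name = "intervals", min_length = 1L) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector without missing values.",
                  name),
          class = "hrvpart_parameter_error")
  }
  if (length(x) < min_length) {
    abort(sprintf("`%s` must have at least %d values, got %d.",
                  name, min_length, length(x)),
          class = "hrvpart_length_error")
  }
  invisible(x)
}

# Set the RNG state only when an explicit seed is given; callers that manage
# their own stream pass seed = NULL.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    assert_count(seed, "seed")
    set.seed(as.integer(seed))
  }
  expr
}
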