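#' Bidirectional stepwise pre-selection of predictors
#'
#' Stepwise multiple linear regression without interactions, starting from
#' the empty model: at each step the candidate with the smallest partial-F
#' p-value enters if it is at or below `p_enter` (0.05), and after every
#' entry any included variable whose p-value exceeds `p_remove` (0.10) is
#' removed, iterating to a fixed point. Ties are broken deterministically by
#' (p-value, then variable name). Used to pre-select, within each variable
#' category, the predictors that go forward to hierarchical partitioning.
#'
#' Complete cases over the response and candidates are used. Zero-variance
#' candidates are dropped with a warning. When the complete-case n is below
#' 10 + (number of candidates), a warning is issued and the candidate set is
#' reduced to the best candidates by univariate p-value until the rule is
#' met.
#'
#' @param df A data frame.
#' @param response Name of the dependent variable (a delta HRV index).
#' @param candidates Character vector of candidate predictor names.
#' @param p_enter Entry threshold on the partial-F p-value.
#' @param p_remove Removal threshold.
#'
#' @return An object of class `"stepwise_selection"`: a list with `selected`
#'   (character), `log` (tibble of step, action, variable, p), `n`
#'   (complete-case n), plus the thresholds and candidate set. [tidy()]
#'   returns the step log, [glance()] a one-row summary.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
#' d$y <- 2 * d$x1 + rnorm(100)
#' stepwise_select(d, "y", c("x1", "x2", "x3"))
stepwise_select <- function(df, response, candidates, p_enter = 0.05,
                            p_remove = 0.10) {
  assert_number(p_enter, "p_enter", lower = 0, upper = 1)
  assert_number(p_remove, "p_remove", lower = 0, upper = 1)
  missing_cols <- setdiff(c(response, candidates), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "hrvpart_parameter_error")
  }
  dat <- df[, c(response, candidates), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  y <- dat[[response]]
  log_rows <- list()
  note <- function(step, action, variable, p) {
    log_rows[[length(log_rows) + 1L]] <<-
      tibble(step = step, action = action, variable = variable, p = p)
  }

  zero_var <- candidates[purrr::map_lgl(candidates,
                                        function(v) var(dat[[v]]) == 0)]
  if (length(zero_var) > 0) {
    warn(paste0("Dropping zero-variance candidate(s): ",
                paste(zero_var, collapse = ", ")))
    candidates <- setdiff(candidates, zero_var)
  }

  result <- function(selected) {
    structure(list(response = response, selected = selected,
                   log = if (length(log_rows)) dplyr::bind_rows(log_rows)
                         else tibble(step = integer(), action = character(),
                                     variable = character(), p = numeric()),
                   n = n, candidates = candidates,
                   p_enter = p_enter, p_remove = p_remove),
              class = "stepwise_selection")
  }

  if (length(candidates) == 0 || n < 3 || var(y) == 0) {
    return(result(character(0)))
  }

  if (n < 10 + length(candidates)) {
    uni_p <- purrr::map_dbl(candidates, function(v) {
      fit <- summary(lm(y ~ dat[[v]]))
      if (nrow(fit$coefficients) < 2) 1 else fit$coefficients[2, 4]
    })
    keep_k <- max(0L, n - 10L)
    ord <- order(uni_p, candidates)
    reduced <- candidates[ord][seq_len(min(keep_k, length(candidates)))]
    warn(sprintf(
      "Complete-case n = %d < 10 + %d candidates; reducing to %d candidate(s) by univariate p.",
      n, length(candidates), length(reduced)))
    candidates <- reduced
    if (length(candidates) == 0) return(result(character(0)))
  }

  coef_p <- function(vars) {
    fit <- lm(stats::reformulate(vars, response), data = dat)
    cf <- summary(fit)$coefficients
    setNames(cf[-1, 4], rownames(cf)[-1])
  }

  included <- character(0)
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > 4L * length(candidates) + 10L) break  # cycling guard
    pool <- setdiff(candidates, included)
    if (length(pool) == 0) break
    entry_p <- purrr::map_dbl(pool, function(v) {
      ps <- coef_p(c(included, v))
      if (!v %in% names(ps) || is.na(ps[[v]])) 1 else ps[[v]]
    })
    ord <- order(entry_p, pool)
    best <- ord[1]
    if (entry_p[best] > p_enter) break
    included <- c(included, pool[best])
    note(step, "add", pool[best], entry_p[best])
    repeat {
      ps <- coef_p(included)
      worst <- which(ps == max(ps))
      worst <- worst[order(names(ps)[worst])][1]
      if (ps[worst] <= p_remove) break
      note(step, "remove", names(ps)[worst], unname(ps[worst]))
      included <- setdiff(included, names(ps)[worst])
      if (length(included) == 0) break
    }
  }
  result(included)
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat("Stepwise selection for", x$response, "\n")
  cat("  complete-case n:", x$n, "\n")
  cat("  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "<none>",
      "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stepwise_selection <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.stepwise_selection <- function(x, ...) {
  tibble(response = x$response, n = x$n,
         n_candidates = length(x$candidates),
         n_selected = length(x$selected))
}

#' Combine per-category selections into one predictor list
#'
#' Takes the stepwise selections made within each variable category and
#' returns their union in a stable order (category order as given, then
#' selection order within category), deduplicated. Categories that selected
#' nothing are simply omitted. More than `max_k` combined predictors is an
#' error, because the partitioner's all-subsets computation grows as 2^k.
#'
#' @param selections A list of `stepwise_selection` objects or character
#'   vectors, in category order.
#' @param max_k Predictor budget (default 12).
#'
#' @return Character vector of predictor names.
#' @export
assemble_predictors <- function(selections, max_k = 12) {
  max_k <- assert_count(max_k, "max_k", lower = 1L)
  if (length(selections) < 1) {
    abort("Need at least one selection.", class = "hrvpart_parameter_error")
  }
  vars <- purrr::map(selections, function(s) {
    if (inherits(s, "stepwise_selection")) s$selected else as.character(s)
  })
  combined <- unique(unlist(vars, use.names = FALSE))
  if (length(combined) > max_k) {
    abort(sprintf("%d combined predictors exceed the budget of %d (2^k subsets).",
                  length(combined), max_k),
          class = "hrvpart_budget_error")
  }
  combined
}
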