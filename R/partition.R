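# Build (y, X) from a data frame: numeric columns only, complete cases.
partition_data <- function(df, response, predictors) {
  missing_cols <- setdiff(c(response, predictors), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "hrvpart_parameter_error")
  }
  dat <- df[, c(response, predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  for (v in names(dat)) {
    if (is.logical(dat[[v]])) dat[[v]] <- as.numeric(dat[[v]])
    if (!is.numeric(dat[[v]])) {
      abort(sprintf("Column `%s` must be numeric (code binary covariables 0/1).", v),
            class = "hrvpart_parameter_error")
    }
  }
  list(y = dat[[response]],
       X = as.matrix(dat[, predictors, drop = FALSE]))
}

# R^2 of every predictor subset, indexed by bitmask + 1 (mask 0 = empty
# model, R^2 = 0). Solved from the centered cross-product matrices, so each
# subset costs one small solve rather than a full refit.
subset_r2_vector <- function(y, X) {
  k <- ncol(X)
  n <- length(y)
  if (k > 12) {
    abort("At most 12 predictors are supported (2^k subsets).",
          class = "hrvpart_budget_error")
  }
  if (n <= k + 2) {
    abort(sprintf("Need n > k + 2 complete cases (n = %d, k = %d).", n, k),
          class = "hrvpart_length_error")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  Cxx <- crossprod(Xc)
  Cxy <- crossprod(Xc, yc)
  r2 <- numeric(2^k)
  if (syy == 0) return(r2)
  for (mask in seq_len(2^k - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) != 0L)
    A <- Cxx[S, S, drop = FALSE]
    b <- Cxy[S, , drop = FALSE]
    beta <- tryCatch(solve(A, b), error = function(e) {
      warn(sprintf("Singular design for subset {%s}; using pseudoinverse.",
                   paste(colnames(X)[S], collapse = ", ")))
      MASS::ginv(A) %*% b
    })
    r2[mask + 1L] <- sum(b * beta) / syy
  }
  r2
}

#' R-squared of every predictor subset
#'
#' Ordinary-least-squares R^2 for all 2^k subsets of the predictors (the
#' empty subset has R^2 = 0), the raw material of hierarchical partitioning.
#' Complete cases are used; singular subsets fall back to a pseudoinverse
#' with a warning.
#'
#' @param df A data frame.
#' @param response Name of the dependent variable.
#' @param predictors Character vector of predictor names (at most 12).
#'
#' @return A tibble with columns `subset` (bitmask over `predictors`),
#'   `predictors` (comma-separated names), `size`, `r2`.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
#' all_subsets_r2(d, "y", c("a", "b"))
all_subsets_r2 <- function(df, response, predictors) {
  pd <- partition_data(df, response, predictors)
  r2 <- subset_r2_vector(pd$y, pd$X)
  k <- length(predictors)
  masks <- 0:(2^k - 1)
  tibble(
    subset = masks,
    predictors = purrr::map_chr(masks, function(m) {
      paste(predictors[bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L],
            collapse = ",")
    }),
    size = purrr::map_int(masks, function(m) {
      sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L)
    }),
    r2 = r2
  )
}

# Shapley/Chevan-Sutherland weights and independent contributions from a
# subset R^2 vector.
independent_from_r2 <- function(r2, k) {
  w <- factorial(0:(k - 1)) * factorial(k - 1:k) / factorial(k)
  masks <- 0:(2^k - 1)
  size <- integer(2^k)
  for (m in seq_len(2^k - 1)) {
    size[m + 1L] <- size[bitwShiftR(m, 1L) + 1L] + bitwAnd(m, 1L)
  }
  purrr::map_dbl(seq_len(k), function(j) {
    bj <- bitwShiftL(1L, j - 1L)
    s0 <- masks[bitwAnd(masks, bj) == 0L]
    gains <- r2[s0 + bj + 1L] - r2[s0 + 1L]
    sum(w[size[s0 + 1L] + 1L] * gains)
  })
}

#' Hierarchical partitioning of regression R-squared
#'
#' Decomposes the full-model R^2 into each predictor's independent
#' contribution I (its R^2 improvement averaged over all submodels, i.e.
#' the Shapley value of the R^2 game, equivalently the Chevan--Sutherland
#' average over hierarchy levels) and joint contribution
#' J = univariate R^2 - I (variance shared with the other predictors;
#' negative for suppressor variables and reported as-is). The independent
#' contributions sum exactly to the full-model R^2.
#'
#' The closed-form subset weighting `w(s) = s! (k - s - 1)! / k!` is used,
#' which is invariant to predictor order; [hier_partition_repeats()]
#' reproduces the literal repeated-run protocol.
#'
#' @inheritParams all_subsets_r2
#'
#' @return An object of class `"hier_partition"` with a `result` tibble
#'   (`predictor`, `independent`, `joint`, `i_pct_r2` = 100 I / sum(I),
#'   `i_pct_abs` = 100 I), the full-model `r_squared`, complete-case `n`,
#'   and the `subsets` table. [tidy()] returns the result tibble,
#'   [glance()] a one-row model summary, and [autoplot()] a bar chart.
#' @export
#' @examples
#' set.seed(2)
#' d <- data.frame(a = rnorm(100), b = rnorm(100))
#' d$y <- d$a + 0.5 * d$b + rnorm(100)
#' hier_partition(d, "y", c("a", "b"))
hier_partition <- function(df, response, predictors) {
  pd <- partition_data(df, response, predictors)
  k <- length(predictors)
  r2 <- subset_r2_vector(pd$y, pd$X)
  indep <- independent_from_r2(r2, k)
  uni <- r2[bitwShiftL(1L, 0:(k - 1)) + 1L]
  total <- r2[2^k]
  result <- tibble(
    predictor = predictors,
    independent = indep,
    joint = uni - indep,
    i_pct_r2 = if (sum(indep) != 0) 100 * indep / sum(indep) else NA_real_,
    i_pct_abs = 100 * indep
  )
  structure(list(result = result, r_squared = total, n = length(pd$y),
                 response = response, repeats = NULL,
                 subsets = all_subsets_tbl(r2, predictors)),
            class = "hier_partition")
}

all_subsets_tbl <- function(r2, predictors) {
  k <- length(predictors)
  masks <- 0:(2^k - 1)
  tibble(
    subset = masks,
    predictors = purrr::map_chr(masks, function(m) {
      paste(predictors[bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L],
            collapse = ",")
    }),
    r2 = r2
  )
}

#' Hierarchical partitioning with repeated predictor-order runs
#'
#' Runs [hier_partition()] on `repeats` random permutations of the predictor
#' columns and averages the independent contributions per predictor. With an
#' exact partitioner the decomposition is order-invariant, so the average
#' equals a single run; the repeated protocol is the convention used with
#' implementations whose per-run rounding drifts for more than 9 predictors,
#' and is kept for fidelity and as a self-check.
#'
#' @inheritParams hier_partition
#' @param repeats Number of permutation runs (default 10).
#' @param seed Optional seed for the permutations.
#'
#' @return A `"hier_partition"` object; `repeats` metadata records the
#'   number of runs.
#' @export
hier_partition_repeats <- function(df, response, predictors, repeats = 10,
                                   seed = NULL) {
  repeats <- assert_count(repeats, "repeats", lower = 1L)
  runs <- with_seed(seed, {
    purrr::map(seq_len(repeats), function(i) {
      perm <- sample(predictors)
      hier_partition(df, response, perm)
    })
  })
  base <- runs[[1]]
  avg <- purrr::map_dfr(runs, function(r) r$result) |>
    dplyr::summarise(independent = mean(.data$independent),
                     joint = mean(.data$joint),
                     .by = "predictor")
  avg <- avg[match(predictors, avg$predictor), ]
  indep <- avg$independent
  result <- tibble(
    predictor = predictors,
    independent = indep,
    joint = avg$joint,
    i_pct_r2 = if (sum(indep) != 0) 100 * indep / sum(indep) else NA_real_,
    i_pct_abs = 100 * indep
  )
  structure(list(result = result, r_squared = base$r_squared, n = base$n,
                 response = response, repeats = repeats,
                 subsets = NULL),
            class = "hier_partition")
}

#' @export
print.hier_partition <- function(x, ...) {
  cat("Hierarchical partitioning of R^2 for", x$response, "\n")
  cat(sprintf("  full-model R^2 = %.4f over n = %d\n", x$r_squared, x$n))
  if (!is.null(x$repeats)) cat("  averaged over", x$repeats, "order permutations\n")
  print(x$result)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hier_partition <- function(x, ...) x$result

#' @exportS3Method generics::glance
glance.hier_partition <- function(x, ...) {
  tibble(response = x$response, r_squared = x$r_squared, n = x$n,
         k = nrow(x$result), repeats = x$repeats %||% 1L)
}

#' Valve-parameter partitioning row for one delta index
#'
#' Runs hierarchical partitioning for one delta HRV index on the combined
#' pre-selected predictors and formats the result as one row of the summary
#' table: the valve parameter present among the predictors (if any), its
#' independent explanatory capacity under both percentage conventions, the
#' covariable list, and the combined-model R^2. More than 9 predictors
#' triggers the repeated-order protocol automatically.
#'
#' @param cohort Cohort data frame.
#' @param delta Name of the delta-index column.
#' @param predictors Combined predictor names (from
#'   [assemble_predictors()]).
#' @param valve_vars Names treated as valve-function parameters.
#' @param repeats Order permutations when more than 9 predictors.
#' @param seed Seed for the permutation runs.
#'
#' @return A one-row tibble: `delta`, `valve_parameter`, `i_pct_abs`,
#'   `i_pct_r2`, `covariables`, `r_squared`, `n`, `k`.
#' @export
partition_cohort <- function(cohort, delta, predictors,
                             valve_vars = c("vmax", "pg_mean", "pg_max",
                                            "ava", "avai"),
                             repeats = 10, seed = NULL) {
  hp <- if (length(predictors) > 9) {
    hier_partition_repeats(cohort, delta, predictors, repeats = repeats,
                           seed = seed)
  } else {
    hier_partition(cohort, delta, predictors)
  }
  valve <- intersect(predictors, valve_vars)
  covs <- setdiff(predictors, valve)
  if (length(valve) == 0) {
    return(tibble(delta = delta, valve_parameter = NA_character_,
                  i_pct_abs = NA_real_, i_pct_r2 = NA_real_,
                  covariables = paste(covs, collapse = ", "),
                  r_squared = hp$r_squared, n = hp$n,
                  k = length(predictors)))
  }
  rows <- hp$result[match(valve, hp$result$predictor), ]
  tibble(delta = delta, valve_parameter = valve,
         i_pct_abs = rows$i_pct_abs, i_pct_r2 = rows$i_pct_r2,
         covariables = paste(covs, collapse = ", "),
         r_squared = hp$r_squared, n = hp$n, k = length(predictors))
}
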