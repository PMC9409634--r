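# Independent oracles used across the test files. These deliberately use
# naive, literal implementations so they share no code path with the
# package internals they check.

# O(n^2) sample-entropy template count: explicit double loop, literal
# Chebyshev distance, self-matches excluded.
sampen_bruteforce <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# R^2 by an independent full refit with lm(), for cross-checking the
# cross-product-matrix solver.
r2_refit <- function(df, response, vars) {
  if (length(vars) == 0) return(0)
  summary(lm(stats::reformulate(vars, response), data = df))$r.squared
}

subset_key <- function(vars) {
  if (length(vars) == 0) "<empty>" else paste(sort(vars), collapse = ",")
}

# Independent contributions by explicit averaging over all k! predictor
# orderings (the literal Shapley construction).
shapley_by_orderings <- function(subsets_r2, predictors) {
  k <- length(predictors)
  lookup <- function(vars) subsets_r2[[subset_key(vars)]]
  orders <- combinat_permutations(predictors)
  I <- setNames(numeric(k), predictors)
  for (ord in orders) {
    prev <- character(0)
    for (v in ord) {
      I[v] <- I[v] + lookup(sort(c(prev, v))) - lookup(prev)
      prev <- c(prev, v)
    }
  }
  I / length(orders)
}

combinat_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# Independent contributions by Chevan-Sutherland level averaging: average
# the R^2 gain of adding predictor j within each hierarchy level (submodel
# size), then average the levels.
shapley_by_levels <- function(subsets_r2, predictors) {
  k <- length(predictors)
  lookup <- function(vars) subsets_r2[[subset_key(vars)]]
  I <- setNames(numeric(k), predictors)
  for (j in predictors) {
    others <- setdiff(predictors, j)
    level_means <- sapply(0:(k - 1), function(h) {
      subs <- if (h == 0) list(character(0)) else
        apply(utils::combn(others, h), 2, identity, simplify = FALSE)
      mean(sapply(subs, function(S) lookup(c(S, j)) - lookup(S)))
    })
    I[j] <- mean(level_means)
  }
  I
}

# Named list subset-R^2 table (key = sorted comma-joined names) built from
# independent lm() refits.
subsets_r2_refit <- function(df, response, predictors) {
  k <- length(predictors)
  out <- list()
  out[[subset_key(character(0))]] <- 0
  for (h in 1:k) {
    combos <- utils::combn(predictors, h)
    for (i in seq_len(ncol(combos))) {
      vars <- combos[, i]
      out[[subset_key(vars)]] <- r2_refit(df, response, vars)
    }
  }
  out
}

# A small cohort-like regression design with controlled correlation.
random_design <- function(n, k, rho = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  common <- rnorm(n)
  X <- sqrt(1 - rho) * Z + sqrt(rho) * common
  colnames(X) <- paste0("x", seq_len(k))
  beta <- seq(1, 0.2, length.out = k)
  y <- drop(X %*% beta) + rnorm(n)
  data.frame(y = y, X)
}
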