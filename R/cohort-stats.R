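#' Bonferroni per-comparison threshold
#'
#' The adjusted per-comparison significance level for a family of pairwise
#' tests, reported to three decimals (e.g. 0.05/3 = 0.017 for three group
#' comparisons).
#'
#' @param n_comparisons Number of pairwise comparisons in the family.
#' @param alpha Family-wise level.
#' @return A single number.
#' @export
bonferroni_threshold <- function(n_comparisons = 3, alpha = 0.05) {
  n_comparisons <- assert_count(n_comparisons, "n_comparisons", lower = 1L)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  round(alpha / n_comparisons, 3)
}

# Anderson-Darling gate for one sample (composite hypothesis, 5% level).
# Groups below n = 8 are inconclusive and treated as non-normal.
ad_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 8 || sd(x) == 0) {
    return(list(normal = FALSE, inconclusive = TRUE, p = NA_real_))
  }
  p <- nortest::ad.test(x)$p.value
  list(normal = p > alpha, inconclusive = FALSE, p = p)
}

#' Per-group normality gate
#'
#' Applies an Anderson--Darling test at the 5% level to each group; the
#' variable is treated as normally distributed only when every group passes.
#' Groups too small to test (n < 8) are flagged inconclusive and force the
#' non-normal branch.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param alpha Test level.
#'
#' @return A list with `normal` (single logical), `per_group` (named
#'   logical), `inconclusive` (named logical), `p` (named numeric).
#' @export
group_normality <- function(values, groups, alpha = 0.05) {
  gs <- split(values, groups)
  res <- purrr::map(gs, ad_gate, alpha = alpha)
  list(
    normal = all(purrr::map_lgl(res, "normal")),
    per_group = purrr::map_lgl(res, "normal"),
    inconclusive = purrr::map_lgl(res, "inconclusive"),
    p = purrr::map_dbl(res, "p")
  )
}

# Drop groups that are entirely missing, with a warning.
drop_empty_groups <- function(values, groups) {
  groups <- factor(groups)
  n_by_group <- tapply(!is.na(values), groups, sum)
  empty <- names(n_by_group)[is.na(n_by_group) | n_by_group == 0]
  if (length(empty) > 0) {
    warn(paste0("Excluding empty group(s): ", paste(empty, collapse = ", ")))
    keep <- !groups %in% empty
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  list(values = values, groups = groups)
}

#' Omnibus group comparison
#'
#' One-way ANOVA when the normality gate passes, Kruskal--Wallis otherwise,
#' and a Pearson chi-square test (no continuity correction) for categorical
#' variables.
#'
#' @inheritParams group_normality
#' @param type `"continuous"` or `"categorical"`.
#' @param normal Normality decision for the continuous branch; computed via
#'   [group_normality()] when `NULL`.
#'
#' @return A list with `p`, `test` (name of the test used), `degenerate`
#'   (TRUE when all values are identical and p is reported as 1).
#' @export
#' @examples
#' # printed three-group smoking counts: 6/22, 26/73, 12/32
#' smoking <- rep(rep(c(1, 0), 3), c(6, 16, 26, 47, 12, 20))
#' grp <- rep(c("NAV", "AVSc", "AVSt"), c(22, 73, 32))
#' omnibus_test(smoking, grp, type = "categorical")$p
omnibus_test <- function(values, groups, type = c("continuous", "categorical"),
                         normal = NULL) {
  type <- match.arg(type)
  cleaned <- drop_empty_groups(values, groups)
  keep <- !is.na(cleaned$values)
  values <- cleaned$values[keep]
  groups <- droplevels(cleaned$groups[keep])
  if (nlevels(groups) < 2) {
    abort("Need at least two non-empty groups.",
          class = "hrvpart_parameter_error")
  }
  if (type == "categorical") {
    tab <- table(groups, values)
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    return(list(p = p, test = "chi-square", degenerate = FALSE))
  }
  if (length(unique(values)) == 1L) {
    return(list(p = 1, test = "degenerate", degenerate = TRUE))
  }
  if (is.null(normal)) normal <- group_normality(values, groups)$normal
  if (normal) {
    p <- anova(lm(values ~ groups))[["Pr(>F)"]][1]
    list(p = p, test = "ANOVA", degenerate = FALSE)
  } else {
    p <- kruskal.test(values, groups)$p.value
    list(p = p, test = "Kruskal-Wallis", degenerate = FALSE)
  }
}

#' Post hoc pairwise comparisons
#'
#' All pairwise group comparisons, using Student's t test (normal),
#' Mann--Whitney (non-normal) or chi-square (categorical) -- the same
#' normality/categorical rule as the omnibus test. A pair is flagged
#' significant when the omnibus p is below 0.05 and the pairwise p is below
#' the Bonferroni per-comparison threshold.
#'
#' @inheritParams omnibus_test
#' @param omnibus_p Omnibus p-value used to gate the significance flags.
#' @param threshold Per-comparison threshold (default
#'   `bonferroni_threshold(number of pairs)`).
#'
#' @return A tibble with columns `group1`, `group2`, `test`, `p`,
#'   `significant`.
#' @export
posthoc_tests <- function(values, groups, type = c("continuous", "categorical"),
                          normal = NULL, omnibus_p = NA_real_,
                          threshold = NULL) {
  type <- match.arg(type)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  threshold <- threshold %||% bonferroni_threshold(length(pairs))
  if (type == "continuous" && is.null(normal)) {
    normal <- group_normality(values, groups)$normal
  }
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (type == "categorical") {
      tab <- table(factor(c(rep(pr[1], length(a)), rep(pr[2], length(b)))),
                   c(a, b))
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi-square"
    } else if (length(unique(c(a, b))) == 1L) {
      p <- 1; test <- "degenerate"
    } else if (normal) {
      p <- t.test(a, b, var.equal = TRUE)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      test <- "Mann-Whitney"
    }
    tibble(group1 = pr[1], group2 = pr[2], test = test, p = p)
  })
  rows$significant <- !is.na(omnibus_p) & omnibus_p < 0.05 &
    !is.na(rows$p) & rows$p < threshold
  rows
}

#' Format a per-group summary cell
#'
#' Mean +/- SD for normally distributed variables, median (p25, p75)
#' otherwise (percentiles by linear interpolation), and count (percent) for
#' categorical variables.
#'
#' @param x Values of one group (numeric, or logical/0-1 for categorical).
#' @param style `"mean_sd"`, `"median_iqr"` or `"count_pct"`.
#' @param digits Decimal places for continuous summaries.
#'
#' @return A list with `label` (the formatted string) and the numeric
#'   summary fields.
#' @export
#' @examples
#' format_summary(c(1, 2, 3), "mean_sd")$label      # "2.0 ± 1.0"
#' format_summary(c(1, 2, 3, 4), "median_iqr")$label
format_summary <- function(x, style = c("mean_sd", "median_iqr", "count_pct"),
                           digits = 1) {
  style <- match.arg(style)
  x <- x[!is.na(x)]
  if (length(x) < 1) {
    return(list(label = NA_character_, n = 0L))
  }
  if (style == "mean_sd") {
    m <- mean(x); s <- sd(x)
    list(label = sprintf("%.*f ± %.*f", digits, m, digits, s),
         mean = m, sd = s, n = length(x))
  } else if (style == "median_iqr") {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(label = sprintf("%.*f (%.*f, %.*f)", digits, q[2], digits, q[1],
                         digits, q[3]),
         median = q[2], p25 = q[1], p75 = q[3], n = length(x))
  } else {
    cnt <- sum(as.numeric(x) != 0)
    list(label = sprintf("%d (%.0f%%)", cnt, 100 * cnt / length(x)),
         count = cnt, percent = 100 * cnt / length(x), n = length(x))
  }
}

#' Three-group comparison table
#'
#' Builds a comparison table in the style of clinical baseline tables: one
#' row per variable with per-group formatted summaries, the omnibus test
#' and its p-value, and Bonferroni-gated pairwise significance flags.
#' Continuous variables are routed through the Anderson--Darling normality
#' gate ([group_normality()]); categorical variables (factors, characters,
#' logicals, or numerics with at most two distinct values, plus anything
#' named in `categorical`) are summarized as count (percent) and compared by
#' chi-square.
#'
#' @param df A data frame with one row per subject.
#' @param vars Character vector of variable names to compare (default: all
#'   columns except the group column).
#' @param group Column holding the group labels (default `group`).
#' @param categorical Optional character vector forcing variables onto the
#'   categorical branch.
#' @param digits Decimal places in formatted summaries.
#'
#' @return A tibble with one row per variable: `variable`, `type`, `test`,
#'   `p`, per-group `summary_*` and `n_*` columns, and per-pair `p_*` and
#'   `sig_*` columns.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)$cohort
#' compare_groups(cohort, vars = c("age", "smoking"))
compare_groups <- function(df, vars = NULL, group = group,
                           categorical = NULL, digits = 1) {
  gcol <- as_name(enquo(group))
  if (!gcol %in% names(df)) {
    abort(sprintf("Group column `%s` not found.", gcol),
          class = "hrvpart_parameter_error")
  }
  g <- factor(df[[gcol]], levels = unique(df[[gcol]]))
  vars <- vars %||% setdiff(names(df), gcol)
  purrr::map_dfr(vars, function(v) {
    x <- df[[v]]
    is_cat <- v %in% categorical || !is.numeric(x) ||
      length(unique(x[!is.na(x)])) <= 2
    if (is_cat && !is.numeric(x)) {
      x <- as.numeric(factor(x)) - 1  # second level is the counted one
    }
    keep <- !is.na(x)
    if (is_cat) {
      norm <- NULL
      type <- "categorical"
      style <- "count_pct"
    } else {
      norm <- group_normality(x[keep], g[keep])
      type <- if (norm$normal) "normal" else "non-normal"
      style <- if (norm$normal) "mean_sd" else "median_iqr"
    }
    omni <- omnibus_test(x, g,
                         type = if (is_cat) "categorical" else "continuous",
                         normal = if (is_cat) NULL else norm$normal)
    ph <- posthoc_tests(x, g,
                        type = if (is_cat) "categorical" else "continuous",
                        normal = if (is_cat) NULL else norm$normal,
                        omnibus_p = omni$p)
    sums <- purrr::map(levels(g), function(l) {
      format_summary(x[keep & g == l], style, digits = digits)
    })
    row <- tibble(variable = v, type = type, test = omni$test, p = omni$p)
    for (i in seq_along(levels(g))) {
      row[[paste0("summary_", levels(g)[i])]] <- sums[[i]]$label
      row[[paste0("n_", levels(g)[i])]] <- sums[[i]]$n
    }
    for (i in seq_len(nrow(ph))) {
      key <- paste0(ph$group1[i], "_vs_", ph$group2[i])
      row[[paste0("p_", key)]] <- ph$p[i]
      row[[paste0("sig_", key)]] <- ph$significant[i]
    }
    row
  })
}
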