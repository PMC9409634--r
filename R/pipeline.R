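#' Pipeline configuration
#'
#' Collects every stage parameter of [run_hrv_pipeline()] with defaults
#' equal to the package's documented design choices. The object serializes
#' losslessly to JSON, so a run can be reproduced from its logged
#' configuration alone.
#'
#' @param seed Integer seed used for the stages that randomize (the
#'   repeated-order partitioning).
#' @param n_beats,skip Segment length and leading intervals to skip when
#'   cutting the analysis segment.
#' @param clean Cleaning thresholds passed to [clean_rr()].
#' @param spectral Welch settings passed to [hrv_spectral()].
#' @param scales DFA box sizes.
#' @param sampen_m,sampen_r_factor Sample-entropy settings.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param max_predictors Partitioner budget.
#' @param partition_repeats Order permutations when more than 9 predictors.
#' @param categories Named list mapping variable-category names to cohort
#'   column names, used for the per-category stepwise pre-selection.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, n_beats = 300, skip = 0,
                            clean = list(min_ms = 300, max_ms = 2000,
                                         rel_tol = 0.2,
                                         max_removed_frac = 0.2),
                            spectral = list(rate = 3, seg_len = 256,
                                            overlap = 0.5),
                            scales = 4:11, sampen_m = 2,
                            sampen_r_factor = 0.2,
                            p_enter = 0.05, p_remove = 0.10,
                            max_predictors = 12, partition_repeats = 10,
                            categories = default_categories()) {
  structure(list(seed = as.integer(seed), n_beats = n_beats, skip = skip,
                 clean = clean, spectral = spectral, scales = scales,
                 sampen_m = sampen_m, sampen_r_factor = sampen_r_factor,
                 p_enter = p_enter, p_remove = p_remove,
                 max_predictors = max_predictors,
                 partition_repeats = partition_repeats,
                 categories = categories),
            class = c("pipeline_config", "list"))
}

#' Default variable taxonomy for per-category stepwise selection
#'
#' @return Named list of cohort column names per category: valve function,
#'   ventricular function, biochemical, anthropometric/clinical, breathing
#'   frequency, inflammatory markers, and the delta of mean NN.
#' @export
default_categories <- function() {
  list(
    valve = c("vmax", "pg_mean", "pg_max", "ava", "avai"),
    ventricular = c("lvef", "lvm", "lvmi", "rwt"),
    biochemical = c("glucose", "hemoglobin", "cholesterol", "triglycerides",
                    "albumin"),
    anthropometric_clinical = c("age", "female", "bmi", "sbp", "dbp",
                                "medication", "smoking", "hypertension",
                                "diabetes"),
    mbf = "mbf",
    inflammatory = c("crp", "ifn_gamma", "il4", "et1", "timp1",
                     "mmp2_timp1"),
    delta_mean_nn = "delta_mean_nn"
  )
}

delta_outcomes <- function() {
  paste0("delta_", c("mean_nn", "sdnn", "rmssd", "pnn20", "lf", "hf", "lfn",
                     "hfn", "lf_hf", "alpha1", "sampen"))
}

#' Run the full orthostatic-HRV analysis pipeline
#'
#' Per subject and posture: NN cleaning ([clean_rr()]) and segment selection
#' ([select_segment()]), then the eleven HRV indices ([hrv_indices()]) and
#' the supine-minus-standing deltas ([hrv_delta()]). Cohort level: the
#' deltas are joined to the covariate table, group-comparison tables are
#' built for covariates and deltas ([compare_groups()]), predictors are
#' pre-selected per category by stepwise regression ([stepwise_select()]),
#' combined ([assemble_predictors()]), and hierarchically partitioned
#' ([partition_cohort()]) for each delta index.
#'
#' Subjects whose series fail quality or length checks in either posture are
#' excluded from the delta analyses (with a named reason) but stay in the
#' covariate comparisons. The pipeline fails only when no subject survives.
#'
#' @param rr Long tibble of beats: `subject_id`, `posture`, `interval_ms`
#'   (plus any extra id columns, e.g. `group`), as from [simulate_study()].
#' @param cohort Covariate table with `subject_id` and `group`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `indices.csv`,
#'   `deltas.csv`, `covariate_comparison.csv`, `delta_comparison.csv`,
#'   `selections.json`, `partition.csv` and `run_log.json`.
#'
#' @return A list with `indices`, `deltas`, `covariate_comparison`,
#'   `delta_comparison`, `selections` (nested list), `partition` (tibble),
#'   `exclusions` (tibble), `config`.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(cohort_params(n_per_group = c(8, 10, 8)),
#'                         seed = 1)
#' res <- run_hrv_pipeline(study$rr, study$cohort)
#' res$partition
#' }
run_hrv_pipeline <- function(rr, cohort, config = pipeline_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  # per-series preprocessing with named exclusions
  exclusions <- list()
  series <- dplyr::group_split(rr, .data$subject_id, .data$posture)
  prepped <- purrr::map(series, function(s) {
    id <- as.character(s$subject_id[1])
    posture <- as.character(s$posture[1])
    res <- tryCatch({
      cleaned <- clean_rr(s$interval_ms,
                          min_ms = config$clean$min_ms,
                          max_ms = config$clean$max_ms,
                          rel_tol = config$clean$rel_tol,
                          max_removed_frac = config$clean$max_removed_frac,
                          series_id = paste(id, posture))
      seg <- select_segment(as.numeric(cleaned), n = config$n_beats,
                            skip = config$skip)
      tibble(subject_id = id, posture = posture,
             n_removed = attr(cleaned, "n_removed"),
             intervals = list(seg))
    }, error = function(e) {
      exclusions[[length(exclusions) + 1L]] <<-
        tibble(subject_id = id, posture = posture,
               reason = conditionMessage(e))
      NULL
    })
    res
  })
  prepped <- dplyr::bind_rows(prepped)
  if (nrow(prepped) == 0) {
    abort("No usable series: every subject failed preprocessing.",
          class = "hrvpart_quality_error")
  }
  # a subject failing either posture leaves the delta analyses
  bad_subjects <- unique(purrr::map_chr(exclusions,
                                        function(e) e$subject_id[1]))
  prepped <- dplyr::filter(prepped, !.data$subject_id %in% bad_subjects)
  if (nrow(prepped) == 0) {
    abort("No subject has two usable postures.",
          class = "hrvpart_quality_error")
  }

  indices <- dplyr::bind_cols(
    prepped[, c("subject_id", "posture", "n_removed")],
    purrr::map_dfr(prepped$intervals, function(x) {
      hrv_indices(x, rate = config$spectral$rate,
                  seg_len = config$spectral$seg_len,
                  overlap = config$spectral$overlap,
                  scales = config$scales, m = config$sampen_m,
                  r_factor = config$sampen_r_factor)
    })
  )
  deltas <- hrv_delta(dplyr::select(indices, -"n_removed"))

  # cohort-level analyses on covariates + computed deltas
  cohort <- dplyr::select(cohort,
                          -dplyr::any_of(setdiff(delta_outcomes(),
                                                 "delta_mean_nn")))
  if ("delta_mean_nn" %in% names(cohort)) {
    cohort$delta_mean_nn <- NULL
  }
  merged <- dplyr::inner_join(cohort,
                              dplyr::mutate(deltas,
                                            subject_id = as.character(.data$subject_id)),
                              by = "subject_id")
  covar_vars <- intersect(unlist(config$categories, use.names = FALSE),
                          names(cohort))
  covariate_comparison <- compare_groups(merged, vars = covar_vars)
  delta_comparison <- compare_groups(merged, vars = intersect(
    delta_outcomes(), names(merged)))

  selections <- list()
  partition_rows <- list()
  for (outcome in intersect(delta_outcomes(), names(merged))) {
    cats <- config$categories
    if (outcome == "delta_mean_nn") cats$delta_mean_nn <- NULL
    sel <- purrr::map(cats, function(vars) {
      vars <- setdiff(intersect(vars, names(merged)), outcome)
      if (length(vars) == 0) return(NULL)
      withCallingHandlers(
        stepwise_select(merged, outcome, vars,
                        p_enter = config$p_enter,
                        p_remove = config$p_remove),
        warning = function(w) invokeRestart("muffleWarning"))
    })
    sel <- purrr::compact(sel)
    selections[[outcome]] <- sel
    combined <- tryCatch(
      assemble_predictors(sel, max_k = config$max_predictors),
      error = function(e) e)
    if (inherits(combined, "error") || length(combined) == 0) {
      reason <- if (inherits(combined, "error")) {
        conditionMessage(combined)
      } else {
        "no predictors selected"
      }
      partition_rows[[outcome]] <- tibble(
        delta = outcome, valve_parameter = NA_character_,
        i_pct_abs = NA_real_, i_pct_r2 = NA_real_,
        covariables = NA_character_, r_squared = NA_real_,
        n = NA_integer_, k = 0L, note = reason)
      next
    }
    row <- tryCatch(
      partition_cohort(merged, outcome, combined,
                       valve_vars = config$categories$valve,
                       repeats = config$partition_repeats,
                       seed = config$seed),
      error = function(e) tibble(
        delta = outcome, valve_parameter = NA_character_,
        i_pct_abs = NA_real_, i_pct_r2 = NA_real_,
        covariables = paste(combined, collapse = ", "),
        r_squared = NA_real_, n = NA_integer_, k = length(combined),
        note = conditionMessage(e)))
    if (!"note" %in% names(row)) row$note <- NA_character_
    partition_rows[[outcome]] <- row
  }
  partition <- dplyr::bind_rows(partition_rows)
  exclusions <- if (length(exclusions)) dplyr::bind_rows(exclusions) else
    tibble(subject_id = character(), posture = character(),
           reason = character())

  result <- list(indices = indices, deltas = deltas,
                 covariate_comparison = covariate_comparison,
                 delta_comparison = delta_comparison,
                 selections = selections, partition = partition,
                 exclusions = exclusions, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(result$indices, p("indices.csv"), progress = FALSE)
  readr::write_csv(result$deltas, p("deltas.csv"), progress = FALSE)
  readr::write_csv(result$covariate_comparison,
                   p("covariate_comparison.csv"), progress = FALSE)
  readr::write_csv(result$delta_comparison, p("delta_comparison.csv"),
                   progress = FALSE)
  sel <- purrr::map(result$selections, function(by_cat) {
    purrr::map(by_cat, function(s) {
      list(selected = s$selected, n = s$n,
           log = as.list(s$log))
    })
  })
  jsonlite::write_json(sel, p("selections.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_csv(result$partition, p("partition.csv"), progress = FALSE)
  log <- list(config = unclass(result$config),
              exclusions = as.list(result$exclusions))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
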