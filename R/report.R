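#' Pipeline orchestration and funnel reporting
#'
#' [run_pipeline()] executes the six algorithm steps in order on a cohort
#' bundle and returns a run object holding the attrition funnel, the review
#' verdicts, growth-category counts and descriptive statistics. Percentages of
#' the short-stature denominator are rendered to one decimal (half-up);
#' within-subset shares to whole percent -- the two formats conventionally
#' used when reporting cohort attrition.
#'
#' @name cli_reporting
NULL

#' Run configuration with the published defaults
#'
#' All thresholds and toggles of the algorithm in one validated list: the
#' short-stature bound (-3.0 SDS, boundary inclusive), the one-year linkage
#' window (symmetric +/-365 days), the BMI malnutrition bound (5th
#' percentile), the GH-response rule (>0.5 SDS within 366 days), the
#' growth-normalization rule, staging recency, code sets and calendars.
#'
#' @param short_stature_z qualifying height z-score bound.
#' @param link_window_days half-window for step-3 linkage.
#' @param bmi_percentile step-4 malnutrition bound.
#' @param pairing_days height/weight pairing window for BMI.
#' @param recency_days staging recency for IGF-1 stratification.
#' @param gh_gain,gh_window_days good-clinical-response rule.
#' @param growth_recovery_z,growth_prior_z growth-normalization rule.
#' @param code_sets secondary-cause ICD-10 prefixes.
#' @param category_sets growth-category ICD-10 prefixes.
#' @param assay_calendar,gh_analyzer_calendar assay/analyzer eras.
#' @param seed integer seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(short_stature_z = -3.0, link_window_days = 365,
                       bmi_percentile = 5, pairing_days = 0,
                       recency_days = 365, gh_gain = 0.5, gh_window_days = 366,
                       growth_recovery_z = -2, growth_prior_z = -3,
                       code_sets = default_code_sets(),
                       category_sets = default_category_code_sets(),
                       assay_calendar = default_assay_calendar(),
                       gh_analyzer_calendar = default_gh_analyzer_calendar(),
                       seed = 1L) {
  if (short_stature_z < -5 || short_stature_z > -1) {
    abort("`short_stature_z` must lie in [-5, -1].", class = "spigfd_spec_error")
  }
  if (link_window_days < 0 || bmi_percentile <= 0 || bmi_percentile >= 100 ||
      gh_gain <= 0 || gh_window_days <= 0) {
    abort("Configuration thresholds outside sane ranges.",
          class = "spigfd_spec_error")
  }
  structure(list(short_stature_z = short_stature_z,
                 link_window_days = link_window_days,
                 bmi_percentile = bmi_percentile, pairing_days = pairing_days,
                 recency_days = recency_days, gh_gain = gh_gain,
                 gh_window_days = gh_window_days,
                 growth_recovery_z = growth_recovery_z,
                 growth_prior_z = growth_prior_z, code_sets = code_sets,
                 category_sets = category_sets,
                 assay_calendar = assay_calendar,
                 gh_analyzer_calendar = gh_analyzer_calendar,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Funnel report with attrition percentages
#'
#' @param n integer stage counts, first entry the denominator stage.
#' @param labels optional stage labels.
#' @return tibble `step`, `label`, `n`, `pct_of_step1` (one decimal, half-up),
#'   `share_of_prev` (whole percent of the preceding stage).
#' @export
#' @examples
#' funnel_report(c(4863, 233, 124, 30, 11))
funnel_report <- function(n, labels = NULL) {
  n <- as.integer(n)
  labels <- labels %||% paste("step", seq_along(n))
  denom <- if (length(n) && n[1] > 0) n[1] else NA_integer_
  prev <- dplyr::lag(n)
  tibble(step = seq_along(n), label = labels, n = n,
         pct_of_step1 = if (is.na(denom)) rep(0, length(n)) else
           round_half_up(100 * n / denom, 1),
         share_of_prev = if_else(is.na(prev) | prev == 0, NA_real_,
                                 round_half_up(100 * n / prev, 0)))
}

#' Render a funnel as a text flow chart
#'
#' @param funnel a [funnel_report()] tibble.
#' @return character vector, one block line per stage.
#' @export
render_flowchart <- function(funnel) {
  sprintf("Step %d | %s: %d (%s%%)", funnel$step, funnel$label, funnel$n,
          formatC(funnel$pct_of_step1, format = "f", digits = 1))
}

FUNNEL_LABELS <- c("short stature (height z <= threshold)",
                   "low IGF-1 (< 2.5th percentile)",
                   "short stature within the linkage window of low IGF-1",
                   "no secondary cause (candidate cases)",
                   "entering trajectory review (GH-sufficient)",
                   "SPIGFD candidates after review")

#' Execute the full six-step pipeline on a cohort
#'
#' Steps 1-4 (short stature, low IGF-1, temporal linkage, secondary-cause
#' exclusion), step 5 (GH-deficiency screen over stimulation tests), step 6
#' (trajectory review and verdicts), growth-category labelling, and the
#' descriptive statistics of the candidate set. The result is a pure function
#' of the cohort, references and configuration.
#'
#' @param cohort an [emr_cohort()].
#' @param growth_ref a [growth_reference()].
#' @param igf1_refs an [igf1_reference()].
#' @param config a [run_config()].
#' @return object of class `spigfd_run`: list with `funnel`, `review` (a
#'   `spigfd_review`), `outcomes` (id + verdict + evidence), `categories`,
#'   `stats`, `candidates`, `exclusions`, `steps` (per-step id/evidence
#'   tables) and `config`.
#' @export
run_pipeline <- function(cohort, growth_ref, igf1_refs,
                         config = run_config()) {
  s1 <- step1_short_stature(cohort, growth_ref,
                            threshold = config$short_stature_z)
  s2 <- step2_low_igf1(cohort, s1, igf1_refs, config$assay_calendar,
                       recency_days = config$recency_days)
  s3 <- step3_temporal_link(s1, s2, window_days = config$link_window_days)
  s4 <- step4_exclude_secondary(cohort, s3, growth_ref,
                                code_sets = config$code_sets,
                                bmi_percentile = config$bmi_percentile,
                                pairing_days = config$pairing_days)
  candidates <- s4$candidates

  categories <- classify_growth_category(cohort, candidates, growth_ref,
                                         category_sets = config$category_sets,
                                         velocity_gain = config$gh_gain,
                                         velocity_window_days = config$gh_window_days)

  # Step 5: exclude GH deficiency determined from stimulation testing;
  # indeterminate (untested) patients remain under review.
  ghd <- gh_deficiency(cohort$labs |>
                         filter(.data$patient_id %in% candidates$patient_id),
                       config$gh_analyzer_calendar)
  deficient_ids <- ghd$patient_id[ghd$is_deficient %in% TRUE]
  reviewed <- candidates |> filter(!.data$patient_id %in% deficient_ids)

  records <- build_review_records(cohort, reviewed, growth_ref, igf1_refs,
                                  config$assay_calendar,
                                  recency_days = config$recency_days)
  review <- step6_review(records)
  ghd_outcomes <- tibble(patient_id = deficient_ids,
                         verdict = rep("excluded_gh_deficient",
                                       length(deficient_ids)),
                         evidence = rep("peak GH below analyzer threshold",
                                        length(deficient_ids)))
  outcomes <- bind_rows(
    review |> as_tibble() |> select("patient_id", "verdict", "evidence"),
    ghd_outcomes) |>
    arrange(.data$patient_id)

  counts <- c(dplyr::n_distinct(s1$patient_id), nrow(s2), nrow(s3),
              nrow(candidates), nrow(reviewed),
              sum(review$verdict == "spigfd_candidate"))
  funnel <- funnel_report(counts, FUNNEL_LABELS)

  stats <- candidate_statistics(cohort, candidates, growth_ref)

  structure(list(funnel = funnel, review = review, outcomes = outcomes,
                 categories = categories, stats = stats,
                 candidates = candidates, exclusions = s4$exclusions,
                 gh_status = ghd,
                 steps = list(step1 = s1, step2 = s2, step3 = s3),
                 config = config),
            class = "spigfd_run")
}

# Mean (SD) age / height z / weight z at the index low IGF-1, follow-up span
# and change in height SDS over follow-up, across candidate cases.
candidate_statistics <- function(cohort, candidates, growth_ref) {
  empty <- tibble(n_candidates = nrow(candidates), mean_age_years = NA_real_,
                  sd_age_years = NA_real_, mean_height_z = NA_real_,
                  sd_height_z = NA_real_, mean_weight_z = NA_real_,
                  sd_weight_z = NA_real_, mean_followup_years = NA_real_,
                  sd_followup_years = NA_real_, mean_delta_height_z = NA_real_,
                  sd_delta_height_z = NA_real_, pct_female = NA_real_)
  if (nrow(candidates) == 0L) return(empty)
  pts <- cohort$patients |>
    filter(.data$patient_id %in% candidates$patient_id)
  idx <- candidates |>
    left_join(select(pts, "patient_id", "sex", "birth_date"), by = "patient_id") |>
    mutate(age_years = age_months_at(.data$birth_date, .data$index_date) / 12)

  hz <- height_z_series(cohort, growth_ref) |>
    filter(.data$patient_id %in% candidates$patient_id)
  span <- hz |>
    group_by(.data$patient_id) |>
    summarise(followup_years = as.numeric(max(.data$date) - min(.data$date)) / 365.25,
              delta_z = last(.data$z, order_by = .data$date) -
                first(.data$z, order_by = .data$date),
              .groups = "drop")

  w <- cohort$observations |>
    filter(.data$kind == "weight_kg",
           .data$patient_id %in% candidates$patient_id) |>
    inner_join(select(idx, "patient_id", "index_date", "sex", "birth_date"),
               by = "patient_id") |>
    mutate(gap = abs(as.numeric(.data$date - .data$index_date))) |>
    group_by(.data$patient_id) |>
    arrange(.data$gap, .data$date, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    mutate(age_months = age_months_at(.data$birth_date, .data$date))
  w$weight_z <- if (nrow(w)) {
    measure_zscore(growth_ref, "weight_for_age", w$sex, w$age_months,
                   w$value, on_out_of_range = "na")$z
  } else numeric(0)

  tibble(
    n_candidates = nrow(candidates),
    mean_age_years = mean(idx$age_years),
    sd_age_years = stats::sd(idx$age_years),
    mean_height_z = mean(candidates$height_z_at_link),
    sd_height_z = stats::sd(candidates$height_z_at_link),
    mean_weight_z = mean(w$weight_z, na.rm = TRUE),
    sd_weight_z = stats::sd(w$weight_z, na.rm = TRUE),
    mean_followup_years = mean(span$followup_years),
    sd_followup_years = stats::sd(span$followup_years),
    mean_delta_height_z = mean(span$delta_z),
    sd_delta_height_z = stats::sd(span$delta_z),
    pct_female = round_half_up(100 * mean(idx$sex == "female"), 0))
}

#' @export
print.spigfd_run <- function(x, ...) {
  cat("SPIGFD screening run\n")
  cat(render_flowchart(x$funnel), sep = "\n")
  inv <- glance(x)
  cat(sprintf("SPIGFD candidate prevalence among reviewed: %s%%\n",
              formatC(inv$prevalence_pct, format = "f", digits = 1)))
  invisible(x)
}

#' Tidy a pipeline run: the attrition funnel
#'
#' @param x a `spigfd_run`.
#' @param ... unused.
#' @return the funnel tibble.
#' @method tidy spigfd_run
#' @export
tidy.spigfd_run <- function(x, ...) x$funnel

#' Glance at a pipeline run
#'
#' @param x a `spigfd_run`.
#' @param ... unused.
#' @return one-row tibble of stage counts, candidate prevalence among the
#'   reviewed set, and candidate descriptive statistics.
#' @method glance spigfd_run
#' @export
glance.spigfd_run <- function(x, ...) {
  n <- x$funnel$n
  reviewed <- n[5]
  tibble(n_short_stature = n[1], n_low_igf1 = n[2], n_linked = n[3],
         n_candidates = n[4], n_reviewed = reviewed, n_spigfd = n[6],
         prevalence_pct = if (reviewed > 0) {
           round_half_up(100 * n[6] / reviewed, 1)
         } else 0) |>
    dplyr::bind_cols(x$stats |> select(-"n_candidates"))
}

#' Plot an attrition funnel
#'
#' @param funnel a [funnel_report()] tibble.
#' @return a ggplot.
#' @export
plot_funnel <- function(funnel) {
  funnel$label <- factor(funnel$label, levels = rev(funnel$label))
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$n, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%.1f%%)", .data$n, .data$pct_of_step1)),
      hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = "patients retained", y = NULL,
                  title = "Screening funnel") +
    ggplot2::theme_minimal()
}

#' Plot growth-category counts (labels may overlap across children)
#'
#' @param categories long label table from [classify_growth_category()].
#' @return a ggplot.
#' @export
plot_categories <- function(categories) {
  counts <- categories |> dplyr::count(.data$category)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n, y = stats::reorder(
    .data$category, .data$n))) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "children (labels may overlap)", y = NULL,
                  title = "Abnormal-growth categories of candidate cases") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for pipeline runs (the funnel)
#'
#' @param object a `spigfd_run`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spigfd_run
#' @export
autoplot.spigfd_run <- function(object, ...) plot_funnel(object$funnel)

#' Write a run report to disk
#'
#' Emits `report.json` (funnel, verdict counts, descriptive statistics,
#' category counts, normalization summary), `funnel.csv`, `candidates.csv`,
#' `categories.csv` and per-step patient-id CSVs. JSON output is
#' deterministic: repeated runs on the same inputs are byte-identical.
#'
#' @param run a `spigfd_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$funnel, file.path(dir, "funnel.csv"), progress = FALSE)
  readr::write_csv(run$candidates, file.path(dir, "candidates.csv"),
                   progress = FALSE)
  readr::write_csv(run$categories, file.path(dir, "categories.csv"),
                   progress = FALSE)
  readr::write_csv(run$outcomes, file.path(dir, "outcomes.csv"),
                   progress = FALSE)
  for (s in names(run$steps)) {
    readr::write_csv(tibble(patient_id = unique(run$steps[[s]]$patient_id)),
                     file.path(dir, paste0(s, "_ids.csv")), progress = FALSE)
  }
  ns <- normalization_summary(run$review)
  report <- list(
    funnel = run$funnel,
    verdict_counts = tidy(run$review),
    statistics = run$stats,
    category_counts = run$categories |> dplyr::count(.data$category),
    normalization = ns)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(dir)
}
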