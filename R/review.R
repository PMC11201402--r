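#' Longitudinal review: GH status, normalization, and final verdicts
#'
#' Candidates surviving the funnel are reviewed against their growth-hormone
#' and IGF-1 trajectories. GH deficiency is a peak stimulation value (clonidine
#' and/or arginine) below an analyzer-era threshold (5.4 ng/mL in the Dxl era,
#' 7.4 ng/mL in the Roche era, strict inequality). A good clinical GH response
#' is an absolute height gain of more than 0.5 SDS within a 12-month window on
#' treatment. IGF-1 normalization is the first not-low result after the index
#' low, labelled on-treatment or spontaneous by GH exposure at that date.
#' Verdict precedence: GH-related exclusion (clinical response or on-treatment
#' IGF-1 normalization) > spontaneous normalization of both growth and IGF-1 >
#' spontaneous IGF-1 only > spontaneous growth only > SPIGFD candidate.
#'
#' @name longitudinal_review
NULL

REVIEW_VERDICTS <- c("spigfd_candidate", "excluded_gh_response",
                     "excluded_spont_igf1", "excluded_spont_both",
                     "excluded_spont_growth", "excluded_gh_deficient",
                     "excluded_other_secondary")

#' Default GH analyzer calendar with deficiency thresholds
#'
#' Dxl analyzers (peak GH deficiency bound 5.4 ng/mL) from 2005 until
#' 2019-11-26, Roche analyzers (bound 7.4 ng/mL) from 2019-11-27 onwards; the
#' switch date belongs to the newer analyzer.
#'
#' @return an [assay_calendar()] with an extra `threshold` column (ng/mL).
#' @export
default_gh_analyzer_calendar <- function() {
  cal <- assay_calendar(tibble(
    assay_id = c("Dxl", "Roche"),
    effective_from = as.Date(c("2005-01-01", "2019-11-27"))))
  cal$threshold <- c(5.4, 7.4)
  cal
}

#' Default IGF-1 assay calendar
#'
#' IDS-iSYS from November 2013, Liaison as of October 2017 (boundary date
#' belongs to the newer assay).
#'
#' @return an [assay_calendar()].
#' @export
default_assay_calendar <- function() {
  assay_calendar(tibble(assay_id = c("IDS-iSYS", "Liaison"),
                        effective_from = as.Date(c("2013-11-01", "2017-10-01"))))
}

# GH therapy exposure intervals from the medication table.
#' GH therapy exposure intervals
#'
#' @param medications medication table of an [emr_cohort()].
#' @return tibble `patient_id`, `start_date`, `end_date` (NA = open-ended).
#' @export
gh_exposure_intervals <- function(medications) {
  medications |>
    filter(.data$drug_class == "gh_therapy") |>
    select("patient_id", "start_date", "end_date")
}

# Height-for-age z series for every patient (unclassifiable ages dropped).
#' Height z-score series for a cohort
#'
#' @param cohort an [emr_cohort()].
#' @param growth_ref a [growth_reference()].
#' @return tibble `patient_id`, `date`, `age_months`, `z`.
#' @export
height_z_series <- function(cohort, growth_ref) {
  h <- cohort$observations |>
    filter(.data$kind == "height_cm") |>
    left_join(select(cohort$patients, "patient_id", "sex", "birth_date"),
              by = "patient_id") |>
    mutate(age_months = age_months_at(.data$birth_date, .data$date))
  if (nrow(h) == 0L) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  age_months = numeric(), z = numeric()))
  }
  h$z <- measure_zscore(growth_ref, "height_for_age", h$sex, h$age_months,
                        h$value, on_out_of_range = "na")$z
  h |>
    filter(!is.na(.data$z)) |>
    select("patient_id", "date", "age_months", "z") |>
    arrange(.data$patient_id, .data$date)
}

# Does one patient's z series contain a pair (t1 < t2, gap <= window) fully
# outside GH exposure with z2 - z1 > gain? Used by growth normalization and
# the pubertal-recovery category rule.
off_gh_gain <- function(series, gh_intervals, gain = 0.5, window_days = 366) {
  if (nrow(series) < 2L) return(FALSE)
  on_gh <- date_in_intervals(series$date, gh_intervals$start_date,
                             gh_intervals$end_date)
  s <- series[!on_gh, ]
  pair_gain(s$date, s$z, gain, window_days)
}

# Any ordered pair within the day window with z gain strictly above `gain`.
pair_gain <- function(dates, z, gain, window_days) {
  n <- length(dates)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    gaps <- as.numeric(dates[(i + 1L):n] - dates[i])
    ok <- gaps > 0 & gaps <= window_days
    if (any(ok & (z[(i + 1L):n] - z[i]) > gain)) return(TRUE)
  }
  FALSE
}

#' Step 5 input: GH-deficiency verdict per patient
#'
#' A patient is GH-deficient when the maximum peak GH across all stimulation
#' tests is strictly below the threshold of the analyzer era of the test
#' achieving that maximum. Patients with no stimulation test are
#' indeterminate (`is_deficient = NA`) and are not excluded on that basis --
#' in practice roughly half of reviewed children never had a stimulation test.
#'
#' @param labs lab table (rows with `analyte == "gh_peak"` and a stimulation
#'   context are used).
#' @param analyzer_calendar calendar with `threshold` column; see
#'   [default_gh_analyzer_calendar()].
#' @return tibble `patient_id`, `max_peak`, `test_date`, `analyzer_id`,
#'   `threshold`, `is_deficient`.
#' @export
gh_deficiency <- function(labs, analyzer_calendar = default_gh_analyzer_calendar()) {
  stim <- labs |>
    filter(.data$analyte == "gh_peak", grepl("^stimulation_", .data$context))
  if (nrow(stim) == 0L) {
    return(tibble(patient_id = character(), max_peak = numeric(),
                  test_date = as.Date(character()), analyzer_id = character(),
                  threshold = numeric(), is_deficient = logical()))
  }
  best <- stim |>
    group_by(.data$patient_id) |>
    arrange(dplyr::desc(.data$value), .data$date, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("patient_id", max_peak = "value", test_date = "date")
  best$analyzer_id <- assay_for_date(analyzer_calendar, best$test_date)
  best$threshold <- analyzer_calendar$threshold[
    match(best$analyzer_id, analyzer_calendar$assay_id)]
  best$is_deficient <- best$max_peak < best$threshold
  arrange(best, .data$patient_id)
}

#' Good clinical response to GH treatment
#'
#' True when some pair of on-treatment height z-scores (t1 < t2, gap at most
#' `window_days`) gains strictly more than `gain` SDS. Patients with fewer
#' than two on-treatment observations are `FALSE` (insufficient data).
#'
#' @param heights_z height z series ([height_z_series()] columns).
#' @param gh_intervals output of [gh_exposure_intervals()].
#' @param gain SDS gain bound, default 0.5.
#' @param window_days pair window, default 366 (a 12-month period, absorbing
#'   leap years).
#' @return tibble `patient_id`, `gh_clinical_response` for every patient with
#'   a GH exposure interval.
#' @export
gh_clinical_response <- function(heights_z, gh_intervals, gain = 0.5,
                                 window_days = 366) {
  ids <- unique(gh_intervals$patient_id)
  res <- purrr::map_lgl(ids, function(pid) {
    iv <- gh_intervals[gh_intervals$patient_id == pid, ]
    s <- heights_z |> filter(.data$patient_id == pid)
    on <- date_in_intervals(s$date, iv$start_date, iv$end_date)
    pair_gain(s$date[on], s$z[on], gain, window_days)
  })
  tibble(patient_id = ids, gh_clinical_response = res) |>
    arrange(.data$patient_id)
}

#' IGF-1 normalization after the index low
#'
#' Finds each patient's first not-low classified result strictly after the
#' first-low index and labels it `on_treatment` when its date falls inside a
#' GH exposure interval, `spontaneous` otherwise; `none` when every subsequent
#' result stays low.
#'
#' @param classifications output of [classify_igf1()] (all of a patient's
#'   classifiable results).
#' @param gh_intervals output of [gh_exposure_intervals()].
#' @return tibble `patient_id`, `normalization` (`none`/`on_treatment`/
#'   `spontaneous`), `normalization_date`, `months_to_normalization`.
#' @export
igf1_normalization <- function(classifications, gh_intervals) {
  idx <- first_low_igf1(classifications)
  if (nrow(idx) == 0L) {
    return(tibble(patient_id = character(), normalization = character(),
                  normalization_date = as.Date(character()),
                  months_to_normalization = numeric()))
  }
  later <- classifications |>
    filter(!.data$unclassifiable) |>
    inner_join(select(idx, "patient_id", index_date = "collection_date",
                      index_id = "result_id"),
               by = "patient_id") |>
    filter(.data$collection_date > .data$index_date, !.data$is_low) |>
    group_by(.data$patient_id) |>
    arrange(.data$collection_date, .data$result_id, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()
  out <- idx |> select("patient_id", index_date = "collection_date")
  out <- out |>
    left_join(select(later, "patient_id",
                     normalization_date = "collection_date"),
              by = "patient_id")
  on_gh <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
    if (is.na(out$normalization_date[i])) return(NA)
    iv <- gh_intervals[gh_intervals$patient_id == out$patient_id[i], ]
    date_in_intervals(out$normalization_date[i], iv$start_date, iv$end_date)
  })
  out |>
    mutate(normalization = dplyr::case_when(
             is.na(.data$normalization_date) ~ "none",
             on_gh ~ "on_treatment",
             TRUE ~ "spontaneous"),
           months_to_normalization = as.numeric(
             .data$normalization_date - .data$index_date) / MONTH_DAYS) |>
    select("patient_id", "normalization", "normalization_date",
           "months_to_normalization") |>
    arrange(.data$patient_id)
}

#' Spontaneous growth normalization
#'
#' The source algorithm names the concept without a formula; the package rule
#' (configurable) is: the latest height z exceeds `recovery_z` after having
#' previously been at or below `prior_z`, or some off-GH-treatment pair gains
#' more than `gain` SDS within `window_days`.
#'
#' @param heights_z height z series.
#' @param gh_intervals output of [gh_exposure_intervals()].
#' @param recovery_z recovery bound, default -2.
#' @param prior_z prior short-stature bound, default -3.
#' @param gain,window_days velocity-recovery rule, defaults 0.5 SDS / 366 days.
#' @return tibble `patient_id`, `growth_normalized` for every patient in the
#'   series.
#' @export
growth_normalization <- function(heights_z, gh_intervals, recovery_z = -2,
                                 prior_z = -3, gain = 0.5, window_days = 366) {
  ids <- unique(heights_z$patient_id)
  res <- purrr::map_lgl(ids, function(pid) {
    s <- heights_z |> filter(.data$patient_id == pid) |> arrange(.data$date)
    if (nrow(s) < 2L) return(FALSE)
    latest <- s$z[nrow(s)]
    was_short <- which(s$z <= prior_z)
    recovered <- length(was_short) > 0 && min(was_short) < nrow(s) &&
      latest > recovery_z
    recovered || off_gh_gain(s, gh_intervals[gh_intervals$patient_id == pid, ],
                             gain = gain, window_days = window_days)
  })
  tibble(patient_id = ids, growth_normalized = res) |> arrange(.data$patient_id)
}

#' Verdict from review evidence flags
#'
#' Vectorized precedence: GH-related exclusion (on treatment with a good
#' clinical height response or IGF-1 normalization on therapy) > spontaneous
#' normalization of both growth and IGF-1 > spontaneous IGF-1 only >
#' spontaneous growth only > SPIGFD candidate.
#'
#' @param gh_treated logical, any GH therapy exposure.
#' @param gh_clinical_response logical, height gain > 0.5 SDS in 12 months on
#'   treatment.
#' @param gh_lab_response logical, IGF-1 normalized on GH therapy.
#' @param spont_growth_norm,spont_igf1_norm logicals.
#' @return character vector of verdicts (see `REVIEW_VERDICTS`).
#' @export
review_verdict <- function(gh_treated, gh_clinical_response, gh_lab_response,
                           spont_growth_norm, spont_igf1_norm) {
  gh_treated <- gh_treated %in% TRUE
  gh_clinical_response <- gh_clinical_response %in% TRUE
  gh_lab_response <- gh_lab_response %in% TRUE
  spont_growth_norm <- spont_growth_norm %in% TRUE
  spont_igf1_norm <- spont_igf1_norm %in% TRUE
  dplyr::case_when(
    gh_treated & (gh_clinical_response | gh_lab_response) ~ "excluded_gh_response",
    spont_growth_norm & spont_igf1_norm ~ "excluded_spont_both",
    spont_igf1_norm ~ "excluded_spont_igf1",
    spont_growth_norm ~ "excluded_spont_growth",
    TRUE ~ "spigfd_candidate")
}

#' Step 6: final review verdicts and normalization summary
#'
#' Applies [review_verdict()] to a table of per-patient review evidence (as
#' computed from a cohort by [build_review_records()], or transcribed from a
#' published chart-review table via [review_fixture()]). Returns one verdict
#' per patient with an evidence string, plus a spontaneous-normalization
#' summary (median and range of months to normalization, over patients with a
#' spontaneous event and a recorded time).
#'
#' @param records tibble with an id column (`patient_id` or `study_id`) and
#'   logical columns `gh_treated`, `gh_clinical_response`, `gh_lab_response`,
#'   `spont_growth_norm`, `spont_igf1_norm`; optionally
#'   `months_to_normalization`.
#' @return tibble of class `spigfd_review`: id, verdict, the evidence flags,
#'   and `evidence` (fired rules). The normalization summary is the
#'   `"normalization_summary"` attribute; see [normalization_summary()].
#' @export
step6_review <- function(records) {
  records <- as_tibble(records)
  id_col <- intersect(c("patient_id", "study_id"), names(records))[1]
  if (is.na(id_col)) {
    abort("`records` needs a `patient_id` or `study_id` column.",
          class = "spigfd_schema_error")
  }
  needed <- c("gh_treated", "gh_clinical_response", "gh_lab_response",
              "spont_growth_norm", "spont_igf1_norm")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing: ", paste(missing_cols, collapse = ", ")),
          class = "spigfd_schema_error")
  }
  out <- records
  out$verdict <- review_verdict(records$gh_treated,
                                records$gh_clinical_response,
                                records$gh_lab_response,
                                records$spont_growth_norm,
                                records$spont_igf1_norm)
  fired <- function(i) {
    rules <- c(
      if (records$gh_clinical_response[i] %in% TRUE) "gh_clinical_response",
      if (records$gh_lab_response[i] %in% TRUE) "igf1_normalized_on_gh",
      if (records$spont_growth_norm[i] %in% TRUE) "spontaneous_growth_normalization",
      if (records$spont_igf1_norm[i] %in% TRUE) "spontaneous_igf1_normalization")
    paste(rules, collapse = "; ")
  }
  out$evidence <- vapply(seq_len(nrow(records)), fired, character(1))

  spont <- out$verdict %in% c("excluded_spont_igf1", "excluded_spont_both")
  months <- if ("months_to_normalization" %in% names(out)) {
    out$months_to_normalization[spont]
  } else numeric(0)
  months <- months[!is.na(months)]
  attr(out, "normalization_summary") <- list(
    n = length(months),
    median_months = if (length(months)) median(months) else NA_real_,
    range_months = if (length(months)) range(months) else c(NA_real_, NA_real_))
  class(out) <- c("spigfd_review", class(out))
  out
}

#' Spontaneous IGF-1 normalization summary of a review
#'
#' @param review a `spigfd_review` from [step6_review()].
#' @return list with `n`, `median_months`, `range_months`.
#' @export
normalization_summary <- function(review) {
  attr(review, "normalization_summary")
}

#' Assemble step-6 review evidence from a cohort
#'
#' Computes, for each candidate, GH exposure, clinical GH response, IGF-1
#' normalization (on-treatment vs spontaneous) and growth normalization from
#' the raw event tables.
#'
#' @param cohort an [emr_cohort()].
#' @param candidates candidate table (needs `patient_id`; typically from
#'   [step4_exclude_secondary()]).
#' @param growth_ref a [growth_reference()].
#' @param igf1_refs an [igf1_reference()].
#' @param calendar an [assay_calendar()].
#' @param recency_days staging recency window for IGF-1 classification.
#' @return evidence tibble suitable for [step6_review()], including
#'   `months_to_normalization`.
#' @export
build_review_records <- function(cohort, candidates, growth_ref, igf1_refs,
                                 calendar, recency_days = 365) {
  ids <- candidates$patient_id
  empty <- tibble(patient_id = character(), gh_treated = logical(),
                  gh_clinical_response = logical(), gh_lab_response = logical(),
                  spont_growth_norm = logical(), spont_igf1_norm = logical(),
                  months_to_normalization = numeric())
  if (length(ids) == 0L) return(empty)

  gh <- gh_exposure_intervals(cohort$medications) |>
    filter(.data$patient_id %in% ids)
  hz <- height_z_series(cohort, growth_ref) |>
    filter(.data$patient_id %in% ids)
  cls <- classify_igf1(cohort$labs |>
                         filter(.data$patient_id %in% ids,
                                .data$context == "basal"),
                       cohort$patients, cohort$staging, igf1_refs, calendar,
                       recency_days = recency_days)
  norm <- igf1_normalization(cls, gh)
  clin <- gh_clinical_response(hz, gh)
  grow <- growth_normalization(hz, gh)

  tibble(patient_id = ids) |>
    mutate(gh_treated = .data$patient_id %in% gh$patient_id) |>
    left_join(clin, by = "patient_id") |>
    left_join(norm, by = "patient_id") |>
    left_join(grow, by = "patient_id") |>
    mutate(
      gh_clinical_response = .data$gh_clinical_response %in% TRUE,
      gh_lab_response = .data$normalization %in% "on_treatment",
      spont_igf1_norm = .data$normalization %in% "spontaneous",
      spont_growth_norm = .data$growth_normalized %in% TRUE,
      months_to_normalization = if_else(.data$spont_igf1_norm,
                                        .data$months_to_normalization,
                                        NA_real_)) |>
    select("patient_id", "gh_treated", "gh_clinical_response",
           "gh_lab_response", "spont_growth_norm", "spont_igf1_norm",
           "months_to_normalization") |>
    arrange(.data$patient_id)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a step-6 review: verdict counts
#'
#' @param x a `spigfd_review`.
#' @param ... unused.
#' @return tibble `verdict`, `n`.
#' @method tidy spigfd_review
#' @export
tidy.spigfd_review <- function(x, ...) {
  tibble(verdict = REVIEW_VERDICTS) |>
    left_join(as_tibble(x) |> dplyr::count(.data$verdict), by = "verdict") |>
    mutate(n = if_else(is.na(.data$n), 0L, .data$n)) |>
    filter(.data$n > 0 | .data$verdict %in% c("spigfd_candidate",
                                              "excluded_gh_response",
                                              "excluded_spont_igf1",
                                              "excluded_spont_both"))
}

#' Glance at a step-6 review: one-row summary
#'
#' @param x a `spigfd_review`.
#' @param ... unused.
#' @return one-row tibble with verdict-class counts, candidate prevalence (%),
#'   and the spontaneous-normalization median/range (months).
#' @method glance spigfd_review
#' @export
glance.spigfd_review <- function(x, ...) {
  v <- x$verdict
  ns <- normalization_summary(x)
  tibble(
    n_reviewed = length(v),
    n_gh_related = sum(v == "excluded_gh_response"),
    n_spont_igf1 = sum(v == "excluded_spont_igf1"),
    n_spont_both = sum(v == "excluded_spont_both"),
    n_spont_growth = sum(v == "excluded_spont_growth"),
    n_spigfd_candidate = sum(v == "spigfd_candidate"),
    prevalence_pct = if (length(v)) {
      round_half_up(100 * sum(v == "spigfd_candidate") / length(v), 1)
    } else NA_real_,
    median_months_to_norm = ns$median_months,
    min_months_to_norm = ns$range_months[1],
    max_months_to_norm = ns$range_months[2])
}
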