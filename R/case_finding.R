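#' Case-finding funnel: steps 1-4
#'
#' The screening funnel retains, in order: (1) children with any height-for-age
#' z-score at or below the short-stature threshold (-3.0 SDS); (2) of those,
#' children with at least one IGF-1 result below the 2.5th-percentile reference
#' bound, indexed at the first recorded low; (3) of those, children whose
#' qualifying short-stature height falls within one year of the index low
#' IGF-1; (4) of those, children with no recorded secondary cause of IGF-1
#' deficiency (ICD-10 code sets for malnutrition, hypothyroidism, GH
#' deficiency/hypopituitarism and liver disease; or BMI below the 5th
#' percentile near the index date, a malnutrition proxy). Step sets are nested
#' by construction. Survivors are candidate cases and receive multi-label
#' growth-category annotations.
#'
#' @name case_finding
NULL

GROWTH_CATEGORIES <- c("transient_pubertal_slowing", "endocrine_disease",
                       "small_for_gestational_age", "genetic_disorder",
                       "idiopathic_short_stature", "medication_adverse_effect")

#' Default ICD-10 prefix sets for secondary causes of IGF-1 deficiency
#'
#' Editable defaults: institutional code lists vary, so these are a starting
#' point, not a canon. Matching is prefix-based after dot-stripping.
#'
#' @return named list of character vectors of ICD-10 prefixes.
#' @export
default_code_sets <- function() {
  list(
    malnutrition = c("E40", "E41", "E42", "E43", "E44", "E45", "E46",
                     "R63.4", "R63.6"),
    hypothyroidism = c("E00", "E01", "E02", "E03"),
    gh_deficiency = "E23.0",
    hypopituitarism = "E23",
    liver_disease = c("K70", "K71", "K72", "K73", "K74", "K75", "K76", "K77"),
    other = character(0)
  )
}

#' Default ICD-10 prefix sets for growth-category labelling
#'
#' Editable defaults used by [classify_growth_category()] to flag endocrine
#' disease (e.g. constitutional delay of growth and puberty E30.0, septo-optic
#' dysplasia Q04.4) and genetic disorders (congenital malformation syndromes,
#' chromosomal anomalies, muscular dystrophies).
#'
#' @return named list with elements `endocrine` and `genetic`.
#' @export
default_category_code_sets <- function() {
  list(
    endocrine = c("E30.0", "Q04.4", "E22", "E34.3"),
    genetic = c("Q87", "Q89.7", "Q9", "G71.0")
  )
}

#' Step 1: short stature
#'
#' A patient qualifies with at least one height observation whose
#' height-for-age z-score is at or below `threshold` (boundary inclusive:
#' z = -3.0 qualifies). Observations whose age falls outside the reference
#' grid are unclassifiable; they are skipped and attached as the `"skipped"`
#' attribute.
#'
#' @param cohort an [emr_cohort()].
#' @param growth_ref a [growth_reference()].
#' @param threshold qualifying height z-score (SDS), default -3.
#' @return tibble of qualifying height observations: `patient_id`, `date`,
#'   `age_months`, `height_cm`, `z`.
#' @export
step1_short_stature <- function(cohort, growth_ref, threshold = -3.0) {
  h <- cohort$observations |>
    filter(.data$kind == "height_cm") |>
    left_join(select(cohort$patients, "patient_id", "sex", "birth_date"),
              by = "patient_id") |>
    mutate(age_months = age_months_at(.data$birth_date, .data$date))
  if (nrow(h) == 0L) {
    out <- tibble(patient_id = character(), date = as.Date(character()),
                  age_months = numeric(), height_cm = numeric(), z = numeric())
    attr(out, "skipped") <- out
    return(out)
  }
  zz <- measure_zscore(growth_ref, "height_for_age", h$sex, h$age_months,
                       h$value, on_out_of_range = "na")
  h$z <- zz$z
  skipped <- h |>
    filter(is.na(.data$z)) |>
    select("patient_id", "date", "age_months", height_cm = "value")
  out <- h |>
    filter(!is.na(.data$z), .data$z <= threshold) |>
    select("patient_id", "date", "age_months", height_cm = "value", "z") |>
    arrange(.data$patient_id, .data$date)
  attr(out, "skipped") <- skipped
  out
}

#' Step 2: low IGF-1 with first-low index
#'
#' Restricts the step-1 patient set to those with at least one low basal IGF-1
#' result and carries each patient's first-low classification as the index.
#'
#' @param cohort an [emr_cohort()].
#' @param step1 output of [step1_short_stature()].
#' @param igf1_refs an [igf1_reference()].
#' @param calendar an [assay_calendar()].
#' @param recency_days staging recency window passed to [classify_igf1()].
#' @return tibble, one row per retained patient: the index classification
#'   (`patient_id`, `index_date`, `result_id`, `value`, `assay_id`,
#'   `stratifier_used`, `threshold_applied`).
#' @export
step2_low_igf1 <- function(cohort, step1, igf1_refs, calendar,
                           recency_days = 365) {
  ids <- unique(step1$patient_id)
  labs <- cohort$labs |>
    filter(.data$patient_id %in% ids, .data$context == "basal")
  cls <- classify_igf1(labs, cohort$patients, cohort$staging, igf1_refs,
                       calendar, recency_days = recency_days)
  first_low_igf1(cls) |>
    select("patient_id", index_date = "collection_date", "result_id",
           "value", "assay_id", "stratifier_used", "threshold_applied")
}

#' Step 3: temporal linkage of short stature and low IGF-1
#'
#' Retains patients with a qualifying height within `window_days` of the index
#' low IGF-1 (symmetric, boundary inclusive: a 365-day gap links, a 366-day
#' gap does not under the default). The linked height is the closest in time;
#' the earlier date wins ties.
#'
#' @param step1 qualifying heights from [step1_short_stature()].
#' @param step2 index classifications from [step2_low_igf1()].
#' @param window_days linkage half-window in days.
#' @return tibble: `patient_id`, `index_date`, `linked_height_date`,
#'   `height_z_at_link`, `gap_days`.
#' @export
step3_temporal_link <- function(step1, step2, window_days = 365) {
  if (nrow(step2) == 0L) {
    return(tibble(patient_id = character(), index_date = as.Date(character()),
                  linked_height_date = as.Date(character()),
                  height_z_at_link = numeric(), gap_days = numeric()))
  }
  step1 |>
    inner_join(select(step2, "patient_id", "index_date"), by = "patient_id") |>
    mutate(gap_days = abs(as.numeric(.data$date - .data$index_date))) |>
    filter(.data$gap_days <= window_days) |>
    group_by(.data$patient_id) |>
    arrange(.data$gap_days, .data$date, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("patient_id", "index_date", linked_height_date = "date",
           height_z_at_link = "z", "gap_days") |>
    arrange(.data$patient_id)
}

#' Step 4: exclude secondary causes of IGF-1 deficiency
#'
#' Excludes a linked patient when (a) any diagnosis (visit diagnosis or
#' problem list, any date -- problem lists are cumulative) matches any
#' secondary-cause ICD-10 prefix, or (b) the BMI-for-age percentile at the
#' encounter nearest the index IGF-1 date is below `bmi_percentile`
#' (malnutrition proxy; heights and weights pair within `pairing_days`).
#' Retained patients are the candidate cases. Every exclusion is logged with
#' the rule and evidence that fired.
#'
#' @param cohort an [emr_cohort()].
#' @param step3 linkage table from [step3_temporal_link()].
#' @param growth_ref a [growth_reference()] (for BMI-for-age).
#' @param code_sets named list of ICD-10 prefix vectors; see
#'   [default_code_sets()].
#' @param bmi_percentile exclusion bound on the BMI percentile, default 5.
#' @param pairing_days height/weight pairing window for BMI, default 0
#'   (same encounter date).
#' @return list with `candidates` (step-3 rows retained, plus `bmi_z_at_index`)
#'   and `exclusions` (`patient_id`, `rule`, `evidence`).
#' @export
step4_exclude_secondary <- function(cohort, step3, growth_ref,
                                    code_sets = default_code_sets(),
                                    bmi_percentile = 5, pairing_days = 0) {
  exclusions <- list()
  ids <- step3$patient_id

  dx <- cohort$diagnoses |> filter(.data$patient_id %in% ids)
  for (set_name in names(code_sets)) {
    hits <- dx[icd10_matches(dx$icd10_code, code_sets[[set_name]]), ]
    if (nrow(hits)) {
      exclusions[[length(exclusions) + 1]] <- hits |>
        group_by(.data$patient_id) |>
        summarise(evidence = paste0(first(.data$icd10_code), " (",
                                    first(.data$source), ", ",
                                    format(first(.data$date)), ")"),
                  .groups = "drop") |>
        mutate(rule = paste0("icd10:", set_name))
    }
  }

  # BMI at the encounter nearest the index date (the study anchors the
  # malnutrition proxy loosely in time; nearest paired encounter is used).
  bmi_z_threshold <- qnorm(bmi_percentile / 100)
  bmi <- pair_bmi(cohort$observations |> filter(.data$patient_id %in% ids),
                  pairing_days = pairing_days)
  bmi_at_index <- bmi |>
    inner_join(select(step3, "patient_id", "index_date"), by = "patient_id") |>
    left_join(select(cohort$patients, "patient_id", "sex", "birth_date"),
              by = "patient_id") |>
    mutate(gap = abs(as.numeric(.data$date - .data$index_date)),
           age_months = age_months_at(.data$birth_date, .data$date)) |>
    group_by(.data$patient_id) |>
    arrange(.data$gap, .data$date, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()
  bmi_at_index$bmi_z <- NA_real_
  if (nrow(bmi_at_index)) {
    zz <- measure_zscore(growth_ref, "bmi_for_age", bmi_at_index$sex,
                         bmi_at_index$age_months, bmi_at_index$bmi,
                         on_out_of_range = "na")
    bmi_at_index$bmi_z <- zz$z
    low_bmi <- bmi_at_index |>
      filter(!is.na(.data$bmi_z), .data$bmi_z < bmi_z_threshold)
    if (nrow(low_bmi)) {
      exclusions[[length(exclusions) + 1]] <- low_bmi |>
        mutate(rule = "bmi_below_percentile",
               evidence = sprintf("BMI z %.2f on %s", .data$bmi_z,
                                  format(.data$date))) |>
        select("patient_id", "rule", "evidence")
    }
  }

  exclusions <- if (length(exclusions)) {
    bind_rows(exclusions) |>
      select("patient_id", "rule", "evidence") |>
      arrange(.data$patient_id, .data$rule)
  } else {
    tibble(patient_id = character(), rule = character(), evidence = character())
  }

  candidates <- step3 |>
    filter(!.data$patient_id %in% exclusions$patient_id) |>
    left_join(select(bmi_at_index, "patient_id", bmi_z_at_index = "bmi_z"),
              by = "patient_id")
  list(candidates = candidates, exclusions = exclusions)
}

#' Multi-label growth-category classification of candidate cases
#'
#' Assigns each candidate any of six abnormal-growth categories:
#' small-for-gestational-age (birth weight and/or length z at or below -2),
#' medication adverse effect (systemic glucocorticoid exposure overlapping the
#' index date), endocrine disease and genetic disorder (configurable ICD-10
#' prefix sets), transient pubertal slowing (a height-SDS gain above
#' `velocity_gain` within `velocity_window_days` off GH therapy at or after the
#' first Tanner stage >= 2 record), and idiopathic short stature (height at or
#' below -2 SDS with no other label). Labels may overlap; a candidate with
#' insufficient inputs may carry no label.
#'
#' @param cohort an [emr_cohort()].
#' @param candidates candidate table from [step4_exclude_secondary()].
#' @param growth_ref a [growth_reference()].
#' @param category_sets see [default_category_code_sets()].
#' @param velocity_gain,velocity_window_days pubertal-recovery rule knobs.
#' @return long tibble (`patient_id`, `category`), one row per label fired.
#' @export
classify_growth_category <- function(cohort, candidates, growth_ref,
                                     category_sets = default_category_code_sets(),
                                     velocity_gain = 0.5,
                                     velocity_window_days = 366) {
  labels <- list()
  add <- function(ids, category) {
    if (length(ids)) {
      labels[[length(labels) + 1]] <<- tibble(patient_id = ids,
                                              category = category)
    }
  }
  ids <- candidates$patient_id
  pts <- cohort$patients |> filter(.data$patient_id %in% ids)

  sga <- pts$patient_id[(!is.na(pts$birth_weight_z) & pts$birth_weight_z <= -2) |
                          (!is.na(pts$birth_length_z) & pts$birth_length_z <= -2)]
  add(sga, "small_for_gestational_age")

  meds <- cohort$medications |>
    filter(.data$patient_id %in% ids,
           .data$drug_class == "systemic_glucocorticoid") |>
    inner_join(select(candidates, "patient_id", "index_date"),
               by = "patient_id") |>
    filter(.data$start_date <= .data$index_date,
           is.na(.data$end_date) | .data$end_date >= .data$index_date)
  add(unique(meds$patient_id), "medication_adverse_effect")

  dx <- cohort$diagnoses |> filter(.data$patient_id %in% ids)
  add(unique(dx$patient_id[icd10_matches(dx$icd10_code,
                                         category_sets$endocrine)]),
      "endocrine_disease")
  add(unique(dx$patient_id[icd10_matches(dx$icd10_code,
                                         category_sets$genetic)]),
      "genetic_disorder")

  hz <- height_z_series(cohort, growth_ref) |>
    filter(.data$patient_id %in% ids)
  gh <- gh_exposure_intervals(cohort$medications)
  pubertal <- cohort$staging |>
    filter(.data$patient_id %in% ids, .data$kind == "tanner_stage",
           .data$value >= 2)
  pubertal_onset <- if (nrow(pubertal)) {
    pubertal |>
      group_by(.data$patient_id) |>
      summarise(onset = min(.data$date), .groups = "drop")
  } else tibble(patient_id = character(), onset = as.Date(character()))
  if (nrow(pubertal_onset)) {
    tps <- purrr::map_lgl(seq_len(nrow(pubertal_onset)), function(i) {
      pid <- pubertal_onset$patient_id[i]
      series <- hz |>
        filter(.data$patient_id == pid,
               .data$date >= pubertal_onset$onset[i])
      off_gh_gain(series, gh[gh$patient_id == pid, ],
                  gain = velocity_gain, window_days = velocity_window_days)
    })
    add(pubertal_onset$patient_id[tps], "transient_pubertal_slowing")
  }

  fired <- if (length(labels)) bind_rows(labels) else
    tibble(patient_id = character(), category = character())

  # ISS: short (<= -2 SDS; always true for funnel survivors) with nothing else
  # identified.
  iss_pool <- if (nrow(hz)) {
    hz |>
      group_by(.data$patient_id) |>
      summarise(min_z = min(.data$z, na.rm = TRUE), .groups = "drop") |>
      filter(.data$min_z <= -2)
  } else tibble(patient_id = character())
  add(setdiff(iss_pool$patient_id, fired$patient_id), "idiopathic_short_stature")

  out <- if (length(labels)) bind_rows(labels) else fired
  out |> distinct() |> arrange(.data$patient_id, .data$category)
}
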