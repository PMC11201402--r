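#' Synthetic EMR cohorts with ground truth
#'
#' The generator emulates a pediatric tertiary-care cohort containing the
#' archetypes the screening algorithm must separate: children of normal
#' stature, short-stature children with normal IGF-1, short children whose low
#' IGF-1 has a secondary cause (exclusion ICD-10 codes or malnutrition-range
#' BMI), constitutional-delay children whose IGF-1 (and sometimes growth)
#' normalizes spontaneously, GH-treated responders, and true-SPIGFD archetypes
#' (persistently low IGF-1, persistent height z within about [-4.2, -3.3],
#' normal GH stimulation, no exclusions). Spontaneous normalization times are
#' drawn log-normally with a configurable median (default 10.8 months)
#' truncated to [6.1, 24.1] months. All randomness is fixed by the spec seed
#' under pinned RNG algorithms, so identical specs give identical bundles.
#'
#' @name synthetic_emr
NULL

ARCHETYPES <- c("normal_stature", "short_stature_only", "secondary_cause",
                "constitutional_delay_normalizer", "gh_responder",
                "true_spigfd")

#' Synthetic LMS growth-reference table
#'
#' A smooth, analytically generated sex x age grid (0-216 months, 12-month
#' steps) of L/M/S parameters for height-, weight- and BMI-for-age. It is a
#' synthetic stand-in with exactly known thresholds, used by tests and the
#' simulator; analyses of real charts must plug in a real national reference
#' via [read_growth_reference()].
#'
#' @return a [growth_reference()].
#' @export
toy_growth_reference <- function() {
  ages <- seq(0, 216, by = 12)
  grids <- lapply(SEXES, function(sx) {
    off <- if (sx == "male") 2 else 0
    bind_rows(
      tibble(measure = "height_for_age", sex = sx, age_months = ages,
             L = 1, M = 50 + off + 112 * (ages / 216)^0.8, S = 0.042),
      tibble(measure = "weight_for_age", sex = sx, age_months = ages,
             L = -0.3, M = 3.4 + off / 4 + 52 * (ages / 216)^1.1, S = 0.12),
      tibble(measure = "bmi_for_age", sex = sx, age_months = ages,
             L = -1.2, M = 16 + 3 * (ages / 216), S = 0.1))
  })
  growth_reference(bind_rows(grids))
}

#' Synthetic IGF-1 reference table
#'
#' Assay-specific 2.5th-percentile lower bounds (ug/L) for both bundled assay
#' ids, stratified by chronological age (six strata to 240 months), Tanner
#' stage and bone age, for both sexes. Synthetic values with a realistic
#' age/puberty shape; real analyses must plug in the laboratory's own package
#' insert via [read_igf1_reference()].
#'
#' @return an [igf1_reference()].
#' @export
toy_igf1_reference <- function() {
  lo <- c(0, 36, 72, 108, 144, 180)
  hi <- c(36, 72, 108, 144, 180, 241)
  base_age <- c(20, 30, 45, 65, 85, 105)
  base_tanner <- c(35, 55, 85, 110, 125)
  rows <- list()
  for (assay in c("IDS-iSYS", "Liaison")) {
    fa <- if (assay == "Liaison") 1.1 else 1
    for (sx in SEXES) {
      fs <- if (sx == "female") 1.05 else 1
      rows[[length(rows) + 1]] <- tibble(
        assay = assay, sex = sx, stratifier = "chronological_age",
        stratum_lo = lo, stratum_hi = hi, p2_5 = base_age * fa * fs)
      rows[[length(rows) + 1]] <- tibble(
        assay = assay, sex = sx, stratifier = "bone_age",
        stratum_lo = lo, stratum_hi = hi, p2_5 = base_age * fa * fs * 0.95)
      rows[[length(rows) + 1]] <- tibble(
        assay = assay, sex = sx, stratifier = "tanner_stage",
        stratum_lo = 1:5, stratum_hi = 1:5, p2_5 = base_tanner * fa * fs)
    }
  }
  igf1_reference(bind_rows(rows))
}

#' Specification of a synthetic cohort
#'
#' @param n_patients cohort size.
#' @param seed integer seed fixing all downstream randomness.
#' @param proportions named archetype mix summing to 1; names must be the six
#'   archetypes.
#' @param norm_median_months median spontaneous IGF-1 normalization time.
#' @param norm_sdlog log-scale spread of the normalization-time log-normal.
#' @param norm_range_months truncation range for normalization times.
#' @param height_noise_cm measurement noise SD on heights (cm).
#' @param igf1_noise_sdlog multiplicative log-scale noise SD on IGF-1.
#' @param visit_interval_months scheduled visit spacing.
#' @param followup_years per-patient follow-up span.
#' @param entry_age_range_months uniform entry-age range.
#' @param study_start,study_end study window (entry dates leave room for the
#'   full follow-up).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200, seed = 1,
                        proportions = c(normal_stature = 0.35,
                                        short_stature_only = 0.20,
                                        secondary_cause = 0.20,
                                        constitutional_delay_normalizer = 0.10,
                                        gh_responder = 0.10,
                                        true_spigfd = 0.05),
                        norm_median_months = 10.8, norm_sdlog = 0.25,
                        norm_range_months = c(6.1, 24.1),
                        height_noise_cm = 0.3, igf1_noise_sdlog = 0.05,
                        visit_interval_months = 6, followup_years = 5,
                        entry_age_range_months = c(24, 150),
                        study_start = as.Date("2013-11-01"),
                        study_end = as.Date("2021-08-31")) {
  if (n_patients < 1) abort("`n_patients` must be >= 1.", class = "spigfd_spec_error")
  if (!setequal(names(proportions), ARCHETYPES)) {
    abort("`proportions` must be named by the six archetypes.",
          class = "spigfd_spec_error")
  }
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    abort("`proportions` must be non-negative and sum to 1.",
          class = "spigfd_spec_error")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 proportions = proportions[ARCHETYPES],
                 norm_median_months = norm_median_months,
                 norm_sdlog = norm_sdlog,
                 norm_range_months = norm_range_months,
                 height_noise_cm = height_noise_cm,
                 igf1_noise_sdlog = igf1_noise_sdlog,
                 visit_interval_months = visit_interval_months,
                 followup_years = followup_years,
                 entry_age_range_months = entry_age_range_months,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end)),
            class = "cohort_spec")
}

# Truncated log-normal normalization time (months).
sample_norm_time <- function(spec) {
  for (i in 1:100) {
    t <- rlnorm(1, meanlog = log(spec$norm_median_months),
                sdlog = spec$norm_sdlog)
    if (t >= spec$norm_range_months[1] && t <= spec$norm_range_months[2]) {
      return(t)
    }
  }
  min(max(t, spec$norm_range_months[1]), spec$norm_range_months[2])
}

# Deterministic archetype counts from the proportion mix.
archetype_counts <- function(proportions, n) {
  cum <- round(cumsum(proportions) * n)
  counts <- diff(c(0, cum))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  setNames(as.integer(counts), names(proportions))
}

#' Generate a synthetic cohort bundle with ground truth
#'
#' @param spec a [cohort_spec()].
#' @return list of class `spigfd_sim`: `cohort` (an [emr_cohort()]), `truth`
#'   (patient_id, archetype, subtype, expected outcome, planted normalization
#'   time), the matching `growth_reference`, `igf1_reference`,
#'   `assay_calendar` and `gh_analyzer_calendar`, and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  growth_ref <- toy_growth_reference()
  igf_ref <- toy_igf1_reference()
  calendar <- default_assay_calendar()
  gh_cal <- default_gh_analyzer_calendar()

  with_seed(spec$seed, {
    n <- spec$n_patients
    counts <- archetype_counts(spec$proportions, n)
    archetypes <- sample(rep(names(counts), counts))
    pid <- sprintf("P%04d", seq_len(n))
    sex <- sample(SEXES, n, replace = TRUE)
    entry_age <- runif(n, spec$entry_age_range_months[1],
                       spec$entry_age_range_months[2])
    entry_span <- as.numeric(spec$study_end - spec$study_start) -
      ceiling(spec$followup_years * 365.25) - 20
    entry_date <- spec$study_start + floor(runif(n, 0, max(entry_span, 1)))
    birth_date <- entry_date - round(entry_age * MONTH_DAYS)

    rows <- purrr::map(seq_len(n), function(i) {
      simulate_patient(pid[i], archetypes[i], sex[i], entry_date[i],
                       birth_date[i], spec, growth_ref, igf_ref, calendar,
                       gh_cal)
    })
    cohort <- emr_cohort(
      patients = bind_rows(purrr::map(rows, "patient")),
      observations = bind_rows(purrr::map(rows, "observations")),
      labs = bind_rows(purrr::map(rows, "labs")),
      diagnoses = bind_rows(purrr::map(rows, "diagnoses")),
      medications = bind_rows(purrr::map(rows, "medications")),
      staging = bind_rows(purrr::map(rows, "staging")))
    truth <- bind_rows(purrr::map(rows, "truth")) |> arrange(.data$patient_id)

    structure(list(cohort = cohort, truth = truth,
                   growth_reference = growth_ref, igf1_reference = igf_ref,
                   assay_calendar = calendar, gh_analyzer_calendar = gh_cal,
                   spec = spec),
              class = "spigfd_sim")
  })
}

# Height value (cm) at a target z for given sex/age, with measurement noise.
planted_height <- function(growth_ref, sex, age_months, z, noise_cm) {
  p <- lookup_lms(growth_ref, "height_for_age", sex, age_months)
  invert_lms(z, p$L, p$M, p$S) + rnorm(length(z), 0, noise_cm)
}

# Weight (kg) hitting a target BMI z at the (already noisy) measured height.
planted_weight <- function(growth_ref, sex, age_months, height_cm, bmi_z) {
  p <- lookup_lms(growth_ref, "bmi_for_age", sex, age_months)
  bmi <- invert_lms(bmi_z, p$L, p$M, p$S)
  bmi * (height_cm / 100)^2 * exp(rnorm(length(bmi_z), 0, 0.01))
}

# The 2.5th-percentile bound the classifier will apply at a visit (the
# generator plants Tanner staging only where it intends that stratifier to
# win, so this mirrors the precedence deterministically).
planted_threshold <- function(igf_ref, calendar, sex, date, age_months,
                              tanner = NA) {
  assay <- assay_for_date(calendar, date)
  if (!is.na(tanner)) {
    lookup_p2_5(igf_ref, assay, sex, "tanner_stage", tanner)
  } else {
    lookup_p2_5(igf_ref, assay, sex, "chronological_age", age_months)
  }
}

simulate_patient <- function(pid, archetype, sex, entry_date, birth_date,
                             spec, growth_ref, igf_ref, calendar, gh_cal) {
  fu_months <- seq(0, spec$followup_years * 12,
                   by = spec$visit_interval_months)
  jitter <- c(0, round(runif(length(fu_months) - 1, -10, 10)))
  dates <- entry_date + round(fu_months * MONTH_DAYS) + jitter
  keep <- dates <= spec$study_end
  dates <- dates[keep]
  m <- as.numeric(dates - entry_date) / MONTH_DAYS
  age <- age_months_at(birth_date, dates)
  nv <- length(dates)

  subtype <- NA_character_
  t_norm <- NA_real_
  bmi_z_target <- rep(0, nv)
  diagnoses <- NULL
  medications <- NULL
  staging <- NULL
  gh_stim <- NULL
  expected <- "screened_out"
  igf_low <- NULL   # logical per visit: plant a low IGF-1 value?
  tanner <- rep(NA_real_, nv)

  if (archetype == "normal_stature") {
    z <- rep(rnorm(1, 0, 0.7), nv)
    igf_low <- rep(FALSE, nv)
    if (runif(1) < 0.3) {
      # Exercise the Tanner-stage stratifier on patients whose outcome it
      # cannot change.
      tanner <- pmin(5, pmax(1, floor(age / 36) - 1))
      staging <- data.frame(patient_id = pid, date = dates, kind = "tanner_stage",
                        value = tanner)
    }
  } else if (archetype == "short_stature_only") {
    z <- rep(runif(1, -3.8, -3.2), nv)
    igf_low <- rep(FALSE, nv)
    if (runif(1) < 0.3) {
      staging <- data.frame(patient_id = pid, date = dates[1],
                        kind = "bone_age_months",
                        value = max(0, age[1] - 12))
    }
  } else if (archetype == "secondary_cause") {
    z <- rep(runif(1, -4.0, -3.2), nv)
    igf_low <- rep(TRUE, nv)
    subtype <- sample(c("malnutrition", "hypothyroidism", "gh_deficiency",
                        "liver_disease", "low_bmi"), 1)
    expected <- "excluded_step4"
    if (subtype == "low_bmi") {
      bmi_z_target <- rep(-2.2, nv)
    } else {
      code <- switch(subtype, malnutrition = "E43",
                     hypothyroidism = "E03.9", gh_deficiency = "E23.0",
                     liver_disease = "K72.9")
      source <- sample(c("visit_diagnosis", "problem_list"), 1)
      diagnoses <- data.frame(patient_id = pid, date = dates[min(2, nv)],
                          icd10_code = code, source = source)
    }
  } else if (archetype == "constitutional_delay_normalizer") {
    z0 <- runif(1, -3.7, -3.25)
    t_norm <- sample_norm_time(spec)
    igf_low <- m < t_norm
    recovers <- runif(1) < 0.5
    if (recovers) {
      # flat at z0 until t_norm, then a linear climb to -1.5 over 42 months
      z <- z0 + pmax(pmin((m - t_norm) / 42, 1), 0) * (-1.5 - z0)
      expected <- "excluded_spont_both"
    } else {
      z <- rep(z0, nv)
      expected <- "excluded_spont_igf1"
    }
    subtype <- if (recovers) "growth_recovery" else "igf1_only"
    diagnoses <- data.frame(patient_id = pid, date = dates[1],
                        icd10_code = "E30.0", source = "problem_list")
  } else if (archetype == "gh_responder") {
    z0 <- runif(1, -3.8, -3.3)
    gh_start <- dates[1] + 61
    gh_end <- gh_start + round(24 * MONTH_DAYS)
    medications <- data.frame(patient_id = pid, start_date = gh_start,
                          end_date = gh_end, drug_class = "gh_therapy")
    on_months <- pmax(pmin(m, 26) - 2, 0)
    z <- pmin(z0 + 0.12 * on_months, z0 + 2.2)
    igf_low <- dates < gh_start
    expected <- "excluded_gh_response"
  } else { # true_spigfd
    z0 <- runif(1, -4.0, -3.5)
    drift <- runif(1, -0.004, 0)
    z <- pmax(z0 + drift * m, -4.4)
    igf_low <- rep(TRUE, nv)
    expected <- "spigfd_candidate"
    stim_date <- dates[1] + 30
    thr <- gh_cal$threshold[match(assay_for_date(gh_cal, stim_date),
                                  gh_cal$assay_id)]
    gh_stim <- data.frame(patient_id = pid,
                      result_id = paste0(pid, "-S01"),
                      date = stim_date, analyte = "gh_peak",
                      value = thr + 2.5,
                      context = sample(c("stimulation_clonidine",
                                         "stimulation_arginine"), 1))
  }

  height <- planted_height(growth_ref, sex, age, z, spec$height_noise_cm)
  weight <- planted_weight(growth_ref, sex, age, height, bmi_z_target)
  observations <- bind_rows(
    data.frame(patient_id = pid, date = dates, kind = "height_cm", value = height),
    data.frame(patient_id = pid, date = dates, kind = "weight_kg", value = weight))

  # Basal IGF-1 at every visit (normal-stature children get fewer draws).
  lab_idx <- if (archetype == "normal_stature") {
    which(runif(nv) < 0.5)
  } else seq_len(nv)
  labs <- NULL
  if (length(lab_idx)) {
    thr <- vapply(lab_idx, function(k) {
      planted_threshold(igf_ref, calendar, sex, dates[k], age[k], tanner[k])
    }, numeric(1))
    factor_low <- ifelse(igf_low[lab_idx], 0.55, 1.45)
    value <- thr * factor_low * exp(rnorm(length(lab_idx), 0,
                                          spec$igf1_noise_sdlog))
    labs <- data.frame(patient_id = pid,
                   result_id = sprintf("%s-L%02d", pid, seq_along(lab_idx)),
                   date = dates[lab_idx], analyte = "igf1", value = value,
                   context = "basal")
  }
  labs <- bind_rows(labs, gh_stim)

  list(
    patient = data.frame(patient_id = pid, sex = sex, birth_date = birth_date,
                     birth_weight_z = rnorm(1, 0, 1),
                     birth_length_z = rnorm(1, 0, 1)),
    observations = observations, labs = labs,
    diagnoses = diagnoses, medications = medications, staging = staging,
    truth = data.frame(patient_id = pid, archetype = archetype, subtype = subtype,
                   expected_outcome = expected, t_norm_months = t_norm,
                   entry_date = entry_date))
}

#' @export
print.spigfd_sim <- function(x, ...) {
  cat("<spigfd_sim> seed", x$spec$seed, "-", x$spec$n_patients, "patients\n")
  print(dplyr::count(x$truth, .data$archetype))
  invisible(x)
}
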