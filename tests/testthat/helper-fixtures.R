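# Shared test fixtures: a small analytic growth reference whose LMS
# parameters are linear in age (so linear interpolation is exact and target
# z-scores can be planted in closed form), a matching one-stratum-rich IGF-1
# reference, and cohort-building shorthand.

# L = 1 everywhere, S = 1/16 (exactly representable), M linear in age:
# z = (value/M - 1) / S, value = M * (1 + S * z) -- closed forms used by the
# tests independently of the package's lookup machinery.
flat_growth_ref <- function() {
  ages <- seq(0, 240, by = 12)
  rows <- lapply(c("male", "female"), function(sx) {
    dplyr::bind_rows(
      tibble::tibble(measure = "height_for_age", sex = sx, age_months = ages,
                     L = 1, M = 70 + 0.5 * ages, S = 0.0625),
      tibble::tibble(measure = "weight_for_age", sex = sx, age_months = ages,
                     L = 1, M = 10 + 0.2 * ages, S = 0.15),
      tibble::tibble(measure = "bmi_for_age", sex = sx, age_months = ages,
                     L = 1, M = 16, S = 0.1))
  })
  growth_reference(dplyr::bind_rows(rows))
}

flat_height_M <- function(age_months) 70 + 0.5 * age_months

# Height value hitting a target z under flat_growth_ref (closed form).
height_at_z <- function(age_months, z) flat_height_M(age_months) * (1 + 0.0625 * z)

# Weight hitting a target BMI z at a given height under flat_growth_ref.
weight_at_bmi_z <- function(height_cm, z) 16 * (1 + 0.1 * z) * (height_cm / 100)^2

# IGF-1 reference: both default assays, one wide age stratum plus Tanner and
# bone-age strata, identical for the sexes.
flat_igf1_ref <- function() {
  rows <- lapply(c("male", "female"), function(sx) {
    dplyr::bind_rows(
      tibble::tibble(assay = "IDS-iSYS", sex = sx,
                     stratifier = "chronological_age",
                     stratum_lo = 0, stratum_hi = 241, p2_5 = 50),
      tibble::tibble(assay = "Liaison", sex = sx,
                     stratifier = "chronological_age",
                     stratum_lo = 0, stratum_hi = 241, p2_5 = 55),
      tibble::tibble(assay = "IDS-iSYS", sex = sx, stratifier = "tanner_stage",
                     stratum_lo = 1:5, stratum_hi = 1:5,
                     p2_5 = c(60, 70, 80, 90, 100)),
      tibble::tibble(assay = "Liaison", sex = sx, stratifier = "tanner_stage",
                     stratum_lo = 1:5, stratum_hi = 1:5,
                     p2_5 = c(66, 77, 88, 99, 110)),
      tibble::tibble(assay = "IDS-iSYS", sex = sx, stratifier = "bone_age",
                     stratum_lo = 0, stratum_hi = 241, p2_5 = 45),
      tibble::tibble(assay = "Liaison", sex = sx, stratifier = "bone_age",
                     stratum_lo = 0, stratum_hi = 241, p2_5 = 49.5))
  })
  igf1_reference(dplyr::bind_rows(rows))
}

# Minimal one-patient building blocks.
mk_patient <- function(id = "P1", sex = "male", birth = "2008-01-01",
                       bw_z = NA_real_, bl_z = NA_real_) {
  tibble::tibble(patient_id = id, sex = sex, birth_date = as.Date(birth),
                 birth_weight_z = bw_z, birth_length_z = bl_z)
}

mk_height <- function(id, dates, values) {
  tibble::tibble(patient_id = id, date = as.Date(dates), kind = "height_cm",
                 value = values)
}

mk_igf1 <- function(id, dates, values, ids = NULL) {
  tibble::tibble(patient_id = id,
                 result_id = ids %||% sprintf("%s-L%02d", id, seq_along(values)),
                 date = as.Date(dates), analyte = "igf1", value = values,
                 context = "basal")
}

`%||%` <- rlang::`%||%`
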