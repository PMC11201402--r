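#' LMS growth-reference tables and anthropometric z-scores
#'
#' Growth references in the LMS parameterization give, for each sex and age, a
#' Box-Cox power `L`, a median `M` and a coefficient of variation `S`. A
#' measurement `x` converts to a standard-deviation score (SDS, z-score)
#'
#'   z = ((x / M)^L - 1) / (L * S)          when |L| is away from zero,
#'   z = log(x / M) / S                     in the L -> 0 limit,
#'
#' which is how height-for-age, weight-for-age and BMI-for-age thresholds such
#' as "height below -3.0 SD" and "BMI below the 5th percentile" are evaluated
#' against national growth charts. Reference tables are user-supplied in a
#' simple tab-separated format; the package bundles small synthetic tables for
#' tests and simulation only.
#'
#' @name lms
NULL

# |L| below this uses the logarithmic branch; keeps the transform continuous
# across the L = 0 singularity.
LMS_LOG_TOL <- 1e-7

GROWTH_MEASURES <- c("height_for_age", "weight_for_age", "bmi_for_age")
SEXES <- c("male", "female")

#' LMS z-score transform
#'
#' @param value measurement in the units of `M` (must be positive).
#' @param L Box-Cox power.
#' @param M reference median (positive, measurement units).
#' @param S coefficient of variation (positive).
#' @return numeric z-score vector.
#' @export
#' @examples
#' zscore_lms(110, L = 1, M = 100, S = 0.1) # 1
zscore_lms <- function(value, L, M, S) {
  if (any(!is.finite(value) | value <= 0)) {
    abort("`value` must be positive and finite.", class = "spigfd_invalid_measurement")
  }
  if (any(!is.finite(M) | M <= 0) || any(!is.finite(S) | S <= 0)) {
    abort("`M` and `S` must be positive and finite.", class = "spigfd_invalid_measurement")
  }
  n <- max(length(value), length(L), length(M), length(S))
  value <- rep_len(value, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- log(value / M) / S
  pw <- abs(L) > LMS_LOG_TOL
  z[pw] <- ((value[pw] / M[pw])^L[pw] - 1) / (L[pw] * S[pw])
  z
}

# Inverse transform: the measurement whose z-score is `z`. Used by the
# synthetic generator to plant trajectories at exact SDS targets.
invert_lms <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  v <- M * exp(S * z)
  pw <- abs(L) > LMS_LOG_TOL
  v[pw] <- M[pw] * (1 + L[pw] * S[pw] * z[pw])^(1 / L[pw])
  v
}

#' Construct and validate a growth-reference table
#'
#' @param x data frame with columns `measure` (one of `height_for_age`,
#'   `weight_for_age`, `bmi_for_age`), `sex` (`male`/`female`), `age_months`,
#'   `L`, `M`, `S`.
#' @return a validated tibble of class `growth_reference`.
#' @export
growth_reference <- function(x) {
  x <- as_tibble(x)
  required <- c("measure", "sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("Growth reference is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "spigfd_schema_error")
  }
  x <- x[required]
  if (!all(x$measure %in% GROWTH_MEASURES)) {
    abort("`measure` must be height_for_age, weight_for_age or bmi_for_age.",
          class = "spigfd_schema_error")
  }
  if (!all(x$sex %in% SEXES)) {
    abort("`sex` must be 'male' or 'female'.", class = "spigfd_schema_error")
  }
  if (any(x$age_months < 0) || any(x$M <= 0) || any(x$S <= 0)) {
    abort("Growth reference rows need age_months >= 0, M > 0 and S > 0.",
          class = "spigfd_schema_error")
  }
  x <- arrange(x, .data$measure, .data$sex, .data$age_months)
  dup <- x |>
    group_by(.data$measure, .data$sex) |>
    summarise(dup = anyDuplicated(.data$age_months) > 0, .groups = "drop")
  if (any(dup$dup)) {
    abort("Duplicate age_months within a (measure, sex) grid.",
          class = "spigfd_schema_error")
  }
  class(x) <- c("growth_reference", class(x))
  x
}

#' Read a growth-reference table from a tab-separated file
#'
#' Expected header: `measure sex age_months L M S`, one row per grid point.
#'
#' @param path file path.
#' @return a `growth_reference` tibble.
#' @export
read_growth_reference <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         measure = readr::col_character(),
                         sex = readr::col_character(),
                         .default = readr::col_double()))
  growth_reference(x)
}

#' Look up LMS parameters at an age, interpolating between grid rows
#'
#' Exact grid ages return the stored row; other ages inside the covered range
#' interpolate `L`, `M`, `S` linearly (componentwise) between the bracketing
#' rows and are flagged `interpolated`. Ages outside the covered range are an
#' error by default -- extrapolating a growth chart silently would corrupt
#' thresholding at the +/-3 SDS tails -- or `NA` rows when
#' `on_out_of_range = "na"` (used by pipeline steps that log and skip).
#'
#' @param ref a `growth_reference`.
#' @param measure,sex,age_months vectors (recycled) identifying the query.
#' @param on_out_of_range `"error"` or `"na"`.
#' @return tibble with columns `L`, `M`, `S`, `source_age_months`,
#'   `interpolated`.
#' @export
lookup_lms <- function(ref, measure, sex, age_months,
                       on_out_of_range = c("error", "na")) {
  on_out_of_range <- match.arg(on_out_of_range)
  q <- tibble(measure = measure, sex = sex, age_months = as.numeric(age_months))
  out <- tibble(L = rep(NA_real_, nrow(q)), M = NA_real_, S = NA_real_,
                source_age_months = q$age_months, interpolated = NA)
  for (key in unique(paste(q$measure, q$sex))) {
    idx <- paste(q$measure, q$sex) == key
    parts <- strsplit(key, " ")[[1]]
    grid <- ref[ref$measure == parts[1] & ref$sex == parts[2], ]
    if (nrow(grid) == 0L) {
      abort(paste0("No reference rows for measure '", parts[1], "', sex '",
                   parts[2], "'."), class = "spigfd_range_error")
    }
    a <- q$age_months[idx]
    lo <- min(grid$age_months); hi <- max(grid$age_months)
    outside <- a < lo | a > hi | !is.finite(a)
    if (any(outside) && on_out_of_range == "error") {
      abort(sprintf(
        "Age %s months outside the covered interval [%g, %g] for %s (%s).",
        paste(signif(a[outside], 6), collapse = ", "), lo, hi,
        parts[1], parts[2]), class = "spigfd_range_error")
    }
    inside <- !outside
    if (any(inside)) {
      ai <- a[inside]
      out$L[idx][inside] <- stats::approx(grid$age_months, grid$L, ai)$y
      out$M[idx][inside] <- stats::approx(grid$age_months, grid$M, ai)$y
      out$S[idx][inside] <- stats::approx(grid$age_months, grid$S, ai)$y
      out$interpolated[idx][inside] <- !(ai %in% grid$age_months)
    }
  }
  out
}

#' Anthropometric z-score and percentile for one or more measurements
#'
#' Composes [lookup_lms()] and [zscore_lms()]; the percentile is the
#' standard-normal cumulative probability of the z-score times 100.
#'
#' @inheritParams lookup_lms
#' @param value measurement values in table units.
#' @return tibble with `z`, `percentile`, `source_age_months`, `interpolated`.
#' @export
#' @examples
#' ref <- toy_growth_reference()
#' measure_zscore(ref, "height_for_age", "female", 60, 100)
measure_zscore <- function(ref, measure, sex, age_months, value,
                           on_out_of_range = c("error", "na")) {
  p <- lookup_lms(ref, measure, sex, age_months,
                  on_out_of_range = on_out_of_range)
  z <- rep(NA_real_, nrow(p))
  ok <- !is.na(p$M)
  if (any(ok)) {
    v <- rep_len(as.numeric(value), nrow(p))
    z[ok] <- zscore_lms(v[ok], p$L[ok], p$M[ok], p$S[ok])
  }
  tibble(z = z, percentile = pnorm(z) * 100,
         source_age_months = p$source_age_months,
         interpolated = p$interpolated)
}

#' Body-mass index from a height/weight pair
#'
#' @param height_cm height in centimetres (positive).
#' @param weight_kg weight in kilograms (positive).
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi_value(100, 16) # 16
bmi_value <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE)) {
    abort("Height and weight must be positive.", class = "spigfd_invalid_measurement")
  }
  weight_kg / (height_cm / 100)^2
}

#' Pair height and weight observations into BMI records
#'
#' Heights and weights are paired within `pairing_days` of each other
#' (default 0: same encounter date). A height with no weight inside the window
#' simply yields no BMI row -- a missing pair is a data gap, not an error.
#' Each height is paired with the nearest eligible weight; earlier dates win
#' ties.
#'
#' @param observations observation table (`patient_id`, `date`, `kind`,
#'   `value`) with kinds `height_cm` and `weight_kg`.
#' @param pairing_days maximum day gap between the paired measurements.
#' @return tibble `patient_id`, `date` (height date), `height_cm`,
#'   `weight_kg`, `bmi`.
#' @export
pair_bmi <- function(observations, pairing_days = 0) {
  h <- observations |>
    filter(.data$kind == "height_cm") |>
    select("patient_id", "date", height_cm = "value")
  w <- observations |>
    filter(.data$kind == "weight_kg") |>
    select("patient_id", weight_date = "date", weight_kg = "value")
  if (nrow(h) == 0L || nrow(w) == 0L) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  height_cm = numeric(), weight_kg = numeric(),
                  bmi = numeric()))
  }
  h |>
    inner_join(w, by = "patient_id", relationship = "many-to-many") |>
    mutate(gap = abs(as.numeric(.data$date - .data$weight_date))) |>
    filter(.data$gap <= pairing_days) |>
    group_by(.data$patient_id, .data$date, .data$height_cm) |>
    arrange(.data$gap, .data$weight_date, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    mutate(bmi = bmi_value(.data$height_cm, .data$weight_kg)) |>
    select("patient_id", "date", "height_cm", "weight_kg", "bmi") |>
    arrange(.data$patient_id, .data$date)
}
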