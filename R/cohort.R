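#' EMR cohort data model
#'
#' A cohort is a bundle of six flat event tables keyed by `patient_id`:
#' patients, anthropometric observations, lab results, diagnoses, medications
#' and pubertal/bone-age staging. The bundle round-trips through one CSV per
#' table with deterministic column order and row sort, so pipelines are
#' reproducible byte for byte. Dates are ISO-8601 calendar dates (chart data
#' are day-resolution).
#'
#' @name ehr_model
NULL

COHORT_TABLES <- c("patients", "observations", "labs", "diagnoses",
                   "medications", "staging")

cohort_schemas <- function() {
  list(
    patients = tibble(patient_id = character(), sex = character(),
                      birth_date = as.Date(character()),
                      birth_weight_z = numeric(), birth_length_z = numeric()),
    observations = tibble(patient_id = character(), date = as.Date(character()),
                          kind = character(), value = numeric()),
    labs = tibble(patient_id = character(), result_id = character(),
                  date = as.Date(character()), analyte = character(),
                  value = numeric(), context = character()),
    diagnoses = tibble(patient_id = character(), date = as.Date(character()),
                       icd10_code = character(), source = character()),
    medications = tibble(patient_id = character(),
                         start_date = as.Date(character()),
                         end_date = as.Date(character()),
                         drug_class = character()),
    staging = tibble(patient_id = character(), date = as.Date(character()),
                     kind = character(), value = numeric())
  )
}

#' Construct an EMR cohort bundle
#'
#' Missing tables default to empty; column types are coerced to the published
#' schema and rows are sorted deterministically.
#'
#' @param patients,observations,labs,diagnoses,medications,staging data frames
#'   following the bundle schema (see [read_cohort()]).
#' @return a list of six tibbles with class `emr_cohort`.
#' @export
emr_cohort <- function(patients = NULL, observations = NULL, labs = NULL,
                       diagnoses = NULL, medications = NULL, staging = NULL) {
  schemas <- cohort_schemas()
  supplied <- list(patients = patients, observations = observations,
                   labs = labs, diagnoses = diagnoses,
                   medications = medications, staging = staging)
  cohort <- lapply(COHORT_TABLES, function(tbl) {
    proto <- schemas[[tbl]]
    x <- supplied[[tbl]]
    if (is.null(x)) return(proto)
    x <- as_tibble(x)
    missing_cols <- setdiff(names(proto), names(x))
    if (tbl == "labs" && "result_id" %in% missing_cols && nrow(x) > 0) {
      x$result_id <- sprintf("r%06d", seq_len(nrow(x)))
      missing_cols <- setdiff(missing_cols, "result_id")
    }
    for (mc in missing_cols) x[[mc]] <- proto[[mc]][NA_integer_][seq_len(nrow(x))]
    x <- x[names(proto)]
    for (cn in names(proto)) {
      if (inherits(proto[[cn]], "Date")) x[[cn]] <- as.Date(x[[cn]])
      # measurements are canonicalized to 6 decimals so CSV bundles
      # round-trip byte-identically
      else if (is.numeric(proto[[cn]])) x[[cn]] <- round(as.numeric(x[[cn]]), 6)
      else x[[cn]] <- as.character(x[[cn]])
    }
    x
  })
  names(cohort) <- COHORT_TABLES
  cohort$patients <- arrange(cohort$patients, .data$patient_id)
  cohort$observations <- arrange(cohort$observations, .data$patient_id,
                                 .data$date, .data$kind)
  cohort$labs <- arrange(cohort$labs, .data$patient_id, .data$date,
                         .data$result_id)
  cohort$diagnoses <- arrange(cohort$diagnoses, .data$patient_id, .data$date,
                              .data$icd10_code)
  cohort$medications <- arrange(cohort$medications, .data$patient_id,
                                .data$start_date, .data$drug_class)
  cohort$staging <- arrange(cohort$staging, .data$patient_id, .data$date,
                            .data$kind)
  structure(cohort, class = "emr_cohort")
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort>", nrow(x$patients), "patients;",
      nrow(x$observations), "observations,", nrow(x$labs), "labs,",
      nrow(x$diagnoses), "diagnoses,", nrow(x$medications), "medications,",
      nrow(x$staging), "staging records\n")
  invisible(x)
}

#' Validate a cohort bundle against the data-model invariants
#'
#' Checks patient-id uniqueness, enum values, sanity bounds (height 30-220 cm,
#' weight 1-250 kg), ICD-10 lexical shape, Tanner range, medication interval
#' ordering, birth date preceding all events, GH peaks carrying a stimulation
#' context, and referential integrity of every event row.
#'
#' @param cohort an [emr_cohort()].
#' @return tibble of failures (`table`, `row`, `message`); zero rows when
#'   valid.
#' @export
validate_cohort <- function(cohort) {
  bad <- list()
  note <- function(tbl, rows, msg) {
    if (length(rows)) {
      bad[[length(bad) + 1]] <<- tibble(table = tbl, row = as.integer(rows),
                                        message = msg)
    }
  }
  p <- cohort$patients
  note("patients", which(duplicated(p$patient_id)), "duplicate patient_id")
  note("patients", which(!p$sex %in% SEXES), "sex must be male/female")
  note("patients", which(is.na(p$birth_date)), "missing birth_date")

  o <- cohort$observations
  note("observations", which(!o$kind %in% c("height_cm", "weight_kg")),
       "kind must be height_cm/weight_kg")
  note("observations", which(is.na(o$value) | o$value <= 0),
       "value must be positive")
  note("observations",
       which(o$kind == "height_cm" & (o$value <= 30 | o$value >= 220)),
       "height outside (30, 220) cm")
  note("observations",
       which(o$kind == "weight_kg" & (o$value <= 1 | o$value >= 250)),
       "weight outside (1, 250) kg")

  l <- cohort$labs
  note("labs", which(!l$analyte %in% c("igf1", "gh_peak")),
       "analyte must be igf1/gh_peak")
  note("labs", which(is.na(l$value) | l$value < 0), "value must be non-negative")
  note("labs", which(!l$context %in% c("basal", "stimulation_clonidine",
                                       "stimulation_arginine",
                                       "on_gh_treatment_flag")),
       "unknown lab context")
  note("labs", which(l$analyte == "gh_peak" &
                       !grepl("^stimulation_", l$context)),
       "gh_peak requires a stimulation context")
  note("labs", which(duplicated(l$result_id)), "duplicate result_id")

  d <- cohort$diagnoses
  note("diagnoses", which(!icd10_valid(d$icd10_code)),
       "icd10_code fails the ICD-10 lexical pattern")
  note("diagnoses", which(!d$source %in% c("visit_diagnosis", "problem_list")),
       "source must be visit_diagnosis/problem_list")

  m <- cohort$medications
  note("medications", which(!m$drug_class %in%
                              c("gh_therapy", "systemic_glucocorticoid", "other")),
       "unknown drug_class")
  note("medications",
       which(!is.na(m$end_date) & m$start_date > m$end_date),
       "start_date after end_date")

  s <- cohort$staging
  note("staging", which(!s$kind %in% c("tanner_stage", "bone_age_months")),
       "kind must be tanner_stage/bone_age_months")
  note("staging", which(s$kind == "tanner_stage" & !s$value %in% 1:5),
       "tanner_stage must be 1..5")
  note("staging", which(s$kind == "bone_age_months" & s$value < 0),
       "bone_age_months must be >= 0")

  birth <- setNames(p$birth_date, p$patient_id)
  event_tables <- list(observations = "date", labs = "date",
                       diagnoses = "date", medications = "start_date",
                       staging = "date")
  for (tbl in names(event_tables)) {
    x <- cohort[[tbl]]
    datecol <- event_tables[[tbl]]
    note(tbl, which(!x$patient_id %in% p$patient_id),
         "patient_id not in patients table")
    known <- x$patient_id %in% p$patient_id
    note(tbl, which(known & x[[datecol]] < birth[x$patient_id]),
         "event precedes birth_date")
  }
  if (length(bad)) bind_rows(bad) else
    tibble(table = character(), row = integer(), message = character())
}

#' Read a cohort bundle from a directory of CSV files
#'
#' Expects `patients.csv`, `observations.csv`, `labs.csv`, `diagnoses.csv`,
#' `medications.csv`, `staging.csv` (missing event files are treated as empty
#' tables). In strict mode (default) any invariant breach aborts with row
#' coordinates; otherwise failures are attached as the `"validation"`
#' attribute.
#'
#' @param dir directory containing the bundle.
#' @param strict abort on any validation failure?
#' @return an `emr_cohort`.
#' @export
read_cohort <- function(dir, strict = TRUE) {
  schemas <- cohort_schemas()
  read_one <- function(tbl) {
    path <- file.path(dir, paste0(tbl, ".csv"))
    if (!file.exists(path)) {
      if (tbl == "patients") {
        abort(paste0("Missing required file: ", path), class = "spigfd_schema_error")
      }
      return(NULL)
    }
    proto <- schemas[[tbl]]
    spec <- lapply(proto, function(col) {
      if (inherits(col, "Date")) readr::col_date()
      else if (is.numeric(col)) readr::col_double()
      else readr::col_character()
    })
    x <- readr::read_csv(path, col_types = do.call(readr::cols, spec),
                         show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(names(proto), names(x))
    optional <- c(patients = "birth_weight_z|birth_length_z",
                  labs = "result_id", medications = "end_date")
    hard_missing <- missing_cols[!grepl(optional[tbl] %||% "^$", missing_cols)]
    if (length(hard_missing)) {
      abort(sprintf("File %s is missing column(s): %s", path,
                    paste(hard_missing, collapse = ", ")),
            class = "spigfd_schema_error")
    }
    x
  }
  tables <- lapply(COHORT_TABLES, read_one)
  names(tables) <- COHORT_TABLES
  cohort <- do.call(emr_cohort, tables)
  report <- validate_cohort(cohort)
  if (strict && nrow(report) > 0) {
    abort(paste0("Cohort validation failed (", nrow(report), " row(s)); first: ",
                 report$table[1], " row ", report$row[1], ": ",
                 report$message[1]),
          class = "spigfd_validation_error", report = report)
  }
  attr(cohort, "validation") <- report
  cohort
}

#' Write a cohort bundle to a directory of CSV files
#'
#' Columns and row sort are deterministic, so write/read round-trips are
#' byte-identical.
#'
#' @param cohort an [emr_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tbl in COHORT_TABLES) {
    readr::write_csv(cohort[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}
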