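#' IGF-1 reference classification
#'
#' Serum IGF-1 is judged "low" when it falls strictly below the 2.5th
#' percentile lower bound of an assay-specific pediatric reference, stratified
#' by sex and by chronological age, bone age, or Tanner stage. Laboratories
#' switch assay platforms over time, so results are classified under the assay
#' in use on the collection date, looked up in an assay calendar. When a
#' pubertal stage or bone-age read is on file close enough to the lab date,
#' it takes precedence over chronological age (puberty shifts IGF-1 norms far
#' more than calendar age does).
#'
#' @name igf1
NULL

STRATIFIERS <- c("tanner_stage", "bone_age", "chronological_age")

#' Construct an assay calendar
#'
#' @param x data frame with columns `assay_id` and `effective_from` (dates,
#'   strictly increasing). The same structure describes GH analyzer eras.
#' @return validated tibble of class `assay_calendar`.
#' @export
#' @examples
#' assay_calendar(data.frame(
#'   assay_id = c("IDS-iSYS", "Liaison"),
#'   effective_from = as.Date(c("2013-11-01", "2017-10-01"))))
assay_calendar <- function(x) {
  x <- as_tibble(x)
  if (!all(c("assay_id", "effective_from") %in% names(x))) {
    abort("Assay calendar needs columns `assay_id` and `effective_from`.",
          class = "spigfd_schema_error")
  }
  x$effective_from <- as.Date(x$effective_from)
  if (nrow(x) == 0L || is.unsorted(x$effective_from, strictly = TRUE)) {
    abort("`effective_from` must be non-empty and strictly increasing.",
          class = "spigfd_schema_error")
  }
  class(x) <- c("assay_calendar", class(x))
  x
}

#' Resolve the assay in effect on a collection date
#'
#' A boundary date belongs to the newer assay (an assay "as of October 2017"
#' owns 2017-10-01).
#'
#' @param calendar an [assay_calendar()].
#' @param date `Date` vector.
#' @return character vector of assay ids.
#' @export
assay_for_date <- function(calendar, date) {
  date <- as.Date(date)
  idx <- findInterval(as.numeric(date), as.numeric(calendar$effective_from))
  if (any(idx == 0L, na.rm = TRUE)) {
    abort(sprintf("Date %s precedes the calendar start (%s).",
                  paste(format(date[idx == 0L]), collapse = ", "),
                  format(calendar$effective_from[1])),
          class = "spigfd_range_error")
  }
  calendar$assay_id[idx]
}

#' Construct and validate an IGF-1 reference table
#'
#' @param x data frame with columns `assay`, `sex`, `stratifier`
#'   (`chronological_age`, `bone_age` or `tanner_stage`), `stratum_lo`,
#'   `stratum_hi` (months, half-open `[lo, hi)`; Tanner strata have
#'   `lo == hi` = the stage) and `p2_5` (the 2.5th-percentile lower bound,
#'   ug/L).
#' @return validated tibble of class `igf1_reference`.
#' @export
igf1_reference <- function(x) {
  x <- as_tibble(x)
  required <- c("assay", "sex", "stratifier", "stratum_lo", "stratum_hi", "p2_5")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("IGF-1 reference is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "spigfd_schema_error")
  }
  x <- x[required]
  if (!all(x$stratifier %in% STRATIFIERS) || !all(x$sex %in% SEXES)) {
    abort("Invalid `stratifier` or `sex` value in IGF-1 reference.",
          class = "spigfd_schema_error")
  }
  if (any(x$p2_5 <= 0)) {
    abort("`p2_5` must be positive.", class = "spigfd_schema_error")
  }
  interval_rows <- x$stratifier != "tanner_stage"
  if (any(x$stratum_lo[interval_rows] >= x$stratum_hi[interval_rows])) {
    abort("Age strata need stratum_lo < stratum_hi.", class = "spigfd_schema_error")
  }
  x <- arrange(x, .data$assay, .data$sex, .data$stratifier, .data$stratum_lo)
  overlap <- x |>
    filter(.data$stratifier != "tanner_stage") |>
    group_by(.data$assay, .data$sex, .data$stratifier) |>
    summarise(bad = any(head(.data$stratum_hi, -1) > .data$stratum_lo[-1]),
              .groups = "drop")
  if (any(overlap$bad)) {
    abort("Overlapping age strata within an (assay, sex, stratifier) group.",
          class = "spigfd_schema_error")
  }
  class(x) <- c("igf1_reference", class(x))
  x
}

#' Read an IGF-1 reference table from a tab-separated file
#'
#' Expected header: `assay sex stratifier stratum_lo stratum_hi p2_5`; Tanner
#' strata may be encoded `T1`..`T5` (with `stratum_lo == stratum_hi`).
#'
#' @param path file path.
#' @return an `igf1_reference` tibble.
#' @export
read_igf1_reference <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  tanner_code <- function(v) {
    as.numeric(ifelse(grepl("^[Tt][1-5]$", v), substring(v, 2), v))
  }
  x$stratum_lo <- tanner_code(x$stratum_lo)
  x$stratum_hi <- tanner_code(x$stratum_hi)
  x$p2_5 <- as.numeric(x$p2_5)
  igf1_reference(x)
}

# 2.5th-percentile bound for one (assay, sex) group under one stratifier.
# `key` is age in months (interval strata, [lo, hi)) or the Tanner stage.
lookup_p2_5 <- function(refs, assay, sex, stratifier, key) {
  g <- refs[refs$assay == assay & refs$sex == sex &
              refs$stratifier == stratifier, ]
  if (nrow(g) == 0L || is.na(key)) return(NA_real_)
  if (stratifier == "tanner_stage") {
    hit <- g$stratum_lo == key
  } else {
    hit <- g$stratum_lo <= key & key < g$stratum_hi
  }
  if (!any(hit)) return(NA_real_)
  g$p2_5[which(hit)[1]]
}

# Nearest staging value of one kind within the recency window of each lab
# date; ties go to the earlier record. `stg` is one patient's staging table.
nearest_staging <- function(stg, kind, lab_date, recency_days) {
  s <- stg[stg$kind == kind, ]
  if (nrow(s) == 0L) return(NA_real_)
  gap <- abs(as.numeric(s$date - lab_date))
  s <- s[gap <= recency_days, ]
  if (nrow(s) == 0L) return(NA_real_)
  gap <- abs(as.numeric(s$date - lab_date))
  ord <- order(gap, s$date)
  s$value[ord[1]]
}

#' Classify basal IGF-1 results against stratified reference bounds
#'
#' Each basal IGF-1 result is matched to the assay in effect on its collection
#' date, then to a reference stratum with precedence Tanner stage > bone age >
#' chronological age -- using whichever staging read exists within
#' `recency_days` of the lab date and has a reference entry. A result with no
#' applicable reference entry is marked unclassifiable and treated as
#' not-low (mirroring a chart-review posture of not excluding on missing
#' references); such rows carry `unclassifiable = TRUE`.
#' `is_low` is a strict inequality: a value exactly at the bound is not low.
#'
#' @param labs lab table rows with `analyte == "igf1"` (columns `patient_id`,
#'   `result_id`, `date`, `value`); other analytes are ignored.
#' @param patients patient table (`patient_id`, `sex`, `birth_date`).
#' @param staging staging table (`patient_id`, `date`, `kind`, `value`) or
#'   `NULL`.
#' @param refs an [igf1_reference()].
#' @param calendar an [assay_calendar()].
#' @param recency_days staging usability window around the lab date.
#' @param precedence stratifier order to try; default Tanner > bone age >
#'   chronological age.
#' @return tibble: `result_id`, `patient_id`, `collection_date`, `value`,
#'   `assay_id`, `stratifier_used`, `threshold_applied`, `is_low`,
#'   `unclassifiable`.
#' @export
classify_igf1 <- function(labs, patients, staging, refs, calendar,
                          recency_days = 365, precedence = STRATIFIERS) {
  stopifnot(all(precedence %in% STRATIFIERS))
  labs <- labs |> filter(.data$analyte == "igf1")
  if (!"result_id" %in% names(labs)) {
    labs$result_id <- sprintf("r%06d", seq_len(nrow(labs)))
  }
  out <- labs |>
    select("result_id", "patient_id", collection_date = "date", "value") |>
    left_join(select(patients, "patient_id", "sex", "birth_date"),
              by = "patient_id")
  if (nrow(out) == 0L) {
    return(tibble(result_id = character(), patient_id = character(),
                  collection_date = as.Date(character()), value = numeric(),
                  assay_id = character(), stratifier_used = character(),
                  threshold_applied = numeric(), is_low = logical(),
                  unclassifiable = logical()))
  }
  out$assay_id <- assay_for_date(calendar, out$collection_date)
  out$age_months <- age_months_at(out$birth_date, out$collection_date)

  if (is.null(staging)) staging <- tibble(patient_id = character(),
                                          date = as.Date(character()),
                                          kind = character(), value = numeric())
  refs_df <- as.data.frame(refs)
  staging_df <- as.data.frame(staging)
  staged_ids <- unique(staging_df$patient_id)

  thr <- rep(NA_real_, nrow(out))
  strat <- rep(NA_character_, nrow(out))

  # Chronological age needs no staging context, so it is vectorized per
  # (assay, sex) group; staging-aware precedence runs row-wise only for
  # patients who actually have staging records.
  chrono <- rep(NA_real_, nrow(out))
  grp <- paste(out$assay_id, out$sex)
  for (g in unique(grp)) {
    parts <- strsplit(g, " ")[[1]]
    rr <- refs_df[refs_df$assay == parts[1] & refs_df$sex == parts[2] &
                    refs_df$stratifier == "chronological_age", ]
    if (nrow(rr) == 0L) next
    rr <- rr[order(rr$stratum_lo), ]
    sel <- grp == g
    k <- findInterval(out$age_months[sel], rr$stratum_lo)
    hit <- k >= 1 & out$age_months[sel] < rr$stratum_hi[pmax(k, 1)]
    vals <- rep(NA_real_, sum(sel))
    vals[hit] <- rr$p2_5[k[hit]]
    chrono[sel] <- vals
  }

  chrono_first <- precedence[1] == "chronological_age" & !is.na(chrono)
  rowwise_idx <- which(out$patient_id %in% staged_ids & !chrono_first)
  thr <- if ("chronological_age" %in% precedence) chrono else thr
  strat[!is.na(thr)] <- "chronological_age"
  for (i in rowwise_idx) {
    stg <- staging_df[staging_df$patient_id == out$patient_id[i], ]
    for (s in precedence) {
      key <- switch(s,
        tanner_stage = nearest_staging(stg, "tanner_stage",
                                       out$collection_date[i], recency_days),
        bone_age = nearest_staging(stg, "bone_age_months",
                                   out$collection_date[i], recency_days),
        chronological_age = out$age_months[i])
      p <- lookup_p2_5(refs_df, out$assay_id[i], out$sex[i], s, key)
      if (!is.na(p)) {
        thr[i] <- p
        strat[i] <- s
        break
      }
    }
    if (is.na(thr[i])) strat[i] <- NA_character_
  }
  out$stratifier_used <- strat
  out$threshold_applied <- thr
  out$unclassifiable <- is.na(thr)
  out$is_low <- !is.na(thr) & out$value < thr
  out |>
    select("result_id", "patient_id", "collection_date", "value", "assay_id",
           "stratifier_used", "threshold_applied", "is_low", "unclassifiable") |>
    arrange(.data$patient_id, .data$collection_date, .data$result_id)
}

#' First recorded low IGF-1 per patient
#'
#' When a patient has more than one low result, the first recorded instance is
#' the index; same-date ties break on `result_id`.
#'
#' @param classifications output of [classify_igf1()].
#' @return tibble with one row per patient who has a low result (the earliest
#'   low classification); patients with no low result are absent.
#' @export
first_low_igf1 <- function(classifications) {
  classifications |>
    filter(.data$is_low) |>
    group_by(.data$patient_id) |>
    arrange(.data$collection_date, .data$result_id, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()
}
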