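# Independent brute-force oracles. These deliberately use plain loops and
# stats::approx directly on the reference tables, sharing no code path with
# the package implementations they check.

# z-score via manual componentwise interpolation + the LMS closed form.
oracle_z <- function(ref, measure, sex, age_months, value) {
  g <- ref[ref$measure == measure & ref$sex == sex, ]
  if (age_months < min(g$age_months) || age_months > max(g$age_months)) {
    return(NA_real_)
  }
  L <- stats::approx(g$age_months, g$L, age_months)$y
  M <- stats::approx(g$age_months, g$M, age_months)$y
  S <- stats::approx(g$age_months, g$S, age_months)$y
  if (abs(L) > 1e-7) ((value / M)^L - 1) / (L * S) else log(value / M) / S
}

# IGF-1 low/not-low labels by exhaustive per-result evaluation.
oracle_classify_igf1 <- function(labs, patients, staging, refs,
                                 calendar, recency_days = 365) {
  labs <- labs[labs$analyte == "igf1", ]
  out <- data.frame(result_id = labs$result_id, is_low = NA,
                    stratifier_used = NA_character_)
  for (i in seq_len(nrow(labs))) {
    p <- patients[patients$patient_id == labs$patient_id[i], ]
    d <- labs$date[i]
    k <- max(which(calendar$effective_from <= d))
    assay <- calendar$assay_id[k]
    age <- as.numeric(d - p$birth_date) / 30.4375
    stg <- staging[staging$patient_id == labs$patient_id[i], ]
    nearest <- function(kind) {
      ss <- stg[stg$kind == kind & abs(as.numeric(stg$date - d)) <= recency_days, ]
      if (nrow(ss) == 0) return(NA_real_)
      ss <- ss[order(abs(as.numeric(ss$date - d)), ss$date), ]
      ss$value[1]
    }
    thr <- NA_real_; used <- NA_character_
    for (s in c("tanner_stage", "bone_age", "chronological_age")) {
      key <- switch(s, tanner_stage = nearest("tanner_stage"),
                    bone_age = nearest("bone_age_months"),
                    chronological_age = age)
      if (is.na(key)) next
      rr <- refs[refs$assay == assay & refs$sex == p$sex &
                   refs$stratifier == s, ]
      hit <- if (s == "tanner_stage") {
        which(rr$stratum_lo == key)
      } else {
        which(rr$stratum_lo <= key & key < rr$stratum_hi)
      }
      if (length(hit)) { thr <- rr$p2_5[hit[1]]; used <- s; break }
    }
    out$is_low[i] <- !is.na(thr) && labs$value[i] < thr
    out$stratifier_used[i] <- used
  }
  out
}

# All-pairs scan: any ordered pair within the window with gain > `gain`.
oracle_pair_gain <- function(dates, z, gain = 0.5, window_days = 366) {
  n <- length(dates)
  found <- FALSE
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gap <- as.numeric(dates[j] - dates[i])
      if (gap > 0 && gap <= window_days && (z[j] - z[i]) > gain) found <- TRUE
    }
  }
  found
}
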