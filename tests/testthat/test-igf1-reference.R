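test_that("assay calendar resolves eras with boundary dates owned by the newer assay", {
  cal <- default_assay_calendar()
  expect_equal(assay_for_date(cal, as.Date("2015-06-01")), "IDS-iSYS")
  expect_equal(assay_for_date(cal, as.Date("2018-01-01")), "Liaison")
  expect_equal(assay_for_date(cal, as.Date("2017-10-01")), "Liaison")
  expect_equal(assay_for_date(cal, as.Date("2017-09-30")), "IDS-iSYS")
  expect_error(assay_for_date(cal, as.Date("2010-01-01")),
               class = "spigfd_range_error")
  # partition: every study date maps to exactly one assay
  dates <- seq(as.Date("2013-11-01"), as.Date("2021-08-31"), by = "15 days")
  ids <- assay_for_date(cal, dates)
  expect_true(all(ids %in% cal$assay_id))
  expect_equal(length(ids), length(dates))
})

test_that("a result exactly at the 2.5th-percentile bound is not low", {
  cls <- classify_igf1(mk_igf1("P1", "2015-03-01", 50), mk_patient("P1"),
                       NULL, flat_igf1_ref(), default_assay_calendar())
  expect_false(cls$is_low)
  expect_equal(cls$threshold_applied, 50)
  just_below <- classify_igf1(mk_igf1("P1", "2015-03-01", 50 - 1e-9),
                              mk_patient("P1"), NULL, flat_igf1_ref(),
                              default_assay_calendar())
  expect_true(just_below$is_low)
})

test_that("Tanner stage takes precedence over bone age and chronological age", {
  staging <- tibble::tibble(
    patient_id = "P1", date = as.Date(c("2015-02-01", "2015-02-15")),
    kind = c("tanner_stage", "bone_age_months"), value = c(2, 60))
  # value 65: low under the Tanner-2 bound (70) but not under bone age (45)
  # or chronological age (50) -- precedence decides
  cls <- classify_igf1(mk_igf1("P1", "2015-03-01", 65), mk_patient("P1"),
                       staging, flat_igf1_ref(), default_assay_calendar())
  expect_equal(cls$stratifier_used, "tanner_stage")
  expect_true(cls$is_low)
  # staging outside the recency window falls back to chronological age
  old <- staging
  old$date <- as.Date("2013-12-01")
  cls2 <- classify_igf1(mk_igf1("P1", "2015-03-01", 65), mk_patient("P1"),
                        old, flat_igf1_ref(), default_assay_calendar())
  expect_equal(cls2$stratifier_used, "chronological_age")
  expect_false(cls2$is_low)
})

test_that("classification matches an exhaustive brute-force oracle", {
  set.seed(13)
  refs <- flat_igf1_ref()
  cal <- default_assay_calendar()
  n_pat <- 20
  patients <- dplyr::bind_rows(lapply(seq_len(n_pat), function(i) {
    mk_patient(sprintf("P%02d", i),
               sex = sample(c("male", "female"), 1),
               birth = as.Date("2004-01-01") + sample(0:3000, 1))
  }))
  labs <- dplyr::bind_rows(lapply(patients$patient_id, function(id) {
    k <- sample(2:6, 1)
    mk_igf1(id, as.Date("2014-06-01") + sample(0:2500, k),
            runif(k, 30, 120))
  }))
  staging <- dplyr::bind_rows(lapply(sample(patients$patient_id, 8), function(id) {
    tibble::tibble(patient_id = id,
                   date = as.Date("2014-06-01") + sample(0:2500, 2),
                   kind = c("tanner_stage", "bone_age_months"),
                   value = c(sample(1:5, 1), runif(1, 10, 230)))
  }))
  got <- classify_igf1(labs, patients, staging, refs, cal)
  want <- oracle_classify_igf1(labs, patients, staging, refs, cal)
  merged <- merge(as.data.frame(got), want, by = "result_id",
                  suffixes = c("_pkg", "_orc"))
  expect_equal(nrow(merged), nrow(labs))
  expect_equal(merged$is_low_pkg, merged$is_low_orc)
  expect_equal(merged$stratifier_used_pkg, merged$stratifier_used_orc)
})

test_that("lowering a value never flips low to not-low", {
  set.seed(17)
  refs <- flat_igf1_ref()
  cal <- default_assay_calendar()
  for (i in 1:20) {
    v <- runif(1, 30, 120)
    a <- classify_igf1(mk_igf1("P1", "2016-01-01", v), mk_patient("P1"),
                       NULL, refs, cal)$is_low
    b <- classify_igf1(mk_igf1("P1", "2016-01-01", v - runif(1, 0, 20)),
                       mk_patient("P1"), NULL, refs, cal)$is_low
    expect_false(a && !b)
  }
})

test_that("first low is the earliest, with same-date ties broken on result id", {
  cls <- classify_igf1(
    mk_igf1("P1", c("2016-07-01", "2015-06-01", "2015-06-01", "2015-01-01"),
            c(20, 30, 25, 200), ids = c("r4", "r2", "r1", "r0")),
    mk_patient("P1"), NULL, flat_igf1_ref(), default_assay_calendar())
  first <- first_low_igf1(cls)
  expect_equal(first$collection_date, as.Date("2015-06-01"))
  expect_equal(first$result_id, "r1")

  none <- first_low_igf1(classify_igf1(mk_igf1("P1", "2016-01-01", 500),
                                       mk_patient("P1"), NULL,
                                       flat_igf1_ref(),
                                       default_assay_calendar()))
  expect_equal(nrow(none), 0L)
})

test_that("results with no applicable reference entry are unclassifiable, not low", {
  refs <- igf1_reference(tibble::tibble(
    assay = "IDS-iSYS", sex = "male", stratifier = "chronological_age",
    stratum_lo = 0, stratum_hi = 120, p2_5 = 50))
  # age ~132 months: outside the only stratum
  cls <- classify_igf1(mk_igf1("P1", "2019-01-01", 10), mk_patient("P1"),
                       NULL, refs,
                       assay_calendar(tibble::tibble(
                         assay_id = "IDS-iSYS",
                         effective_from = as.Date("2013-11-01"))))
  expect_true(cls$unclassifiable)
  expect_false(cls$is_low)
})

test_that("IGF-1 reference files round-trip with Tanner stratum codes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay\tsex\tstratifier\tstratum_lo\tstratum_hi\tp2_5",
               "IDS-iSYS\tmale\tchronological_age\t0\t120\t42.5",
               "IDS-iSYS\tmale\ttanner_stage\tT2\tT2\t61"), path)
  ref <- read_igf1_reference(path)
  expect_equal(nrow(ref), 2L)
  expect_equal(ref$stratum_lo[ref$stratifier == "tanner_stage"], 2)
  expect_equal(ref$p2_5, c(42.5, 61))
  # overlapping strata are rejected
  expect_error(igf1_reference(tibble::tibble(
    assay = "A", sex = "male", stratifier = "chronological_age",
    stratum_lo = c(0, 100), stratum_hi = c(120, 200), p2_5 = c(50, 60))),
    class = "spigfd_schema_error")
})
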