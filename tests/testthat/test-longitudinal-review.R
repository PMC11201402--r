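ref <- flat_growth_ref()

stim_lab <- function(id, date, peak, context = "stimulation_clonidine") {
  tibble::tibble(patient_id = id, result_id = paste0(id, "-s", date),
                 date = as.Date(date), analyte = "gh_peak", value = peak,
                 context = context)
}

test_that("GH deficiency uses the analyzer-era threshold with a strict bound", {
  expect_true(gh_deficiency(stim_lab("P1", "2018-05-01", 5.0))$is_deficient)  # Dxl
  expect_false(gh_deficiency(stim_lab("P1", "2018-05-01", 5.4))$is_deficient)
  expect_true(gh_deficiency(stim_lab("P1", "2020-05-01", 7.0))$is_deficient)  # Roche
  expect_false(gh_deficiency(stim_lab("P1", "2020-05-01", 7.4))$is_deficient)
  # the maximum peak across tests decides, under its own test's era
  two <- dplyr::bind_rows(stim_lab("P1", "2018-05-01", 5.0),
                          stim_lab("P1", "2020-05-01", 7.0,
                                   "stimulation_arginine"))
  verdict <- gh_deficiency(two)
  expect_equal(verdict$max_peak, 7.0)
  expect_equal(verdict$analyzer_id, "Roche")
  expect_true(verdict$is_deficient)
  # no stimulation test: indeterminate, absent from the table
  expect_equal(nrow(gh_deficiency(mk_igf1("P1", "2018-01-01", 50))), 0L)
})

gh_iv <- function(id, start, end) {
  tibble::tibble(patient_id = id, start_date = as.Date(start),
                 end_date = as.Date(end))
}

zser <- function(id, dates, z) {
  tibble::tibble(patient_id = id, date = as.Date(dates),
                 age_months = 60, z = z)
}

test_that("good clinical GH response needs > 0.5 SDS gain within 12 months on therapy", {
  iv <- gh_iv("P1", "2016-01-01", "2019-01-01")
  # -3.5 -> -2.9 over 10 months on treatment
  up <- zser("P1", c("2016-02-01", "2016-12-01"), c(-3.5, -2.9))
  expect_true(gh_clinical_response(up, iv)$gh_clinical_response)
  # gain of only 0.4 over 12 months
  flat <- zser("P1", c("2016-02-01", "2017-02-01"), c(-3.5, -3.1))
  expect_false(gh_clinical_response(flat, iv)$gh_clinical_response)
  # the same gain off treatment does not count
  off <- zser("P1", c("2015-01-01", "2015-11-01"), c(-3.5, -2.9))
  expect_false(gh_clinical_response(off, iv)$gh_clinical_response)
  # fewer than two on-treatment points: insufficient data, not a response
  one <- zser("P1", "2016-02-01", -3.5)
  expect_false(gh_clinical_response(one, iv)$gh_clinical_response)
})

test_that("clinical response agrees with a brute-force all-pairs scan", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    dates <- sort(as.Date("2016-01-01") + sample(0:1400, n))
    z <- runif(n, -4, -1)
    iv <- gh_iv("P1", "2016-01-01", "2019-12-31")
    got <- gh_clinical_response(zser("P1", dates, z), iv)$gh_clinical_response
    on <- dates >= iv$start_date & dates <= iv$end_date
    expect_equal(got, oracle_pair_gain(dates[on], z[on]))
  }
})

test_that("IGF-1 normalization is labelled by GH exposure at the event date", {
  refs <- flat_igf1_ref(); cal <- default_assay_calendar()
  # low at entry, first not-low ~10.8 months later, no GH: spontaneous
  d0 <- as.Date("2015-01-01")
  d1 <- d0 + round(10.8 * 30.4375)
  cls <- classify_igf1(mk_igf1("P1", c(d0, d1), c(30, 80)), mk_patient("P1"),
                       NULL, refs, cal)
  none_gh <- gh_iv(character(0), character(0), character(0))
  norm <- igf1_normalization(cls, none_gh)
  expect_equal(norm$normalization, "spontaneous")
  expect_equal(norm$months_to_normalization, 10.8, tolerance = 0.01)
  # same event inside a GH interval: on_treatment
  norm_gh <- igf1_normalization(cls, gh_iv("P1", d0 + 30, d1 + 300))
  expect_equal(norm_gh$normalization, "on_treatment")
  # all results low: none
  cls_low <- classify_igf1(mk_igf1("P1", c(d0, d1), c(30, 25)),
                           mk_patient("P1"), NULL, refs, cal)
  expect_equal(igf1_normalization(cls_low, none_gh)$normalization, "none")
})

test_that("growth normalization: recovery above -2 after <= -3, or off-GH velocity gain", {
  none_gh <- gh_iv(character(0), character(0), character(0))
  up <- zser("P1", c("2015-01-01", "2016-06-01"), c(-3.2, -1.8))
  expect_true(growth_normalization(up, none_gh)$growth_normalized)
  flat <- zser("P1", c("2015-01-01", "2016-06-01", "2017-06-01"),
               c(-3.3, -3.3, -3.3))
  expect_false(growth_normalization(flat, none_gh)$growth_normalized)
  # velocity gain > 0.5 within 12 months while still below -2 also counts
  dip <- zser("P1", c("2015-01-01", "2015-10-01"), c(-3.4, -2.7))
  expect_true(growth_normalization(dip, none_gh)$growth_normalized)
  # but the same gain on GH therapy is not spontaneous
  expect_false(growth_normalization(
    dip, gh_iv("P1", "2014-12-01", "2016-12-01"))$growth_normalized)
})

test_that("verdict precedence and determinism under permuted inputs", {
  rec <- review_fixture()
  rv <- step6_review(rec)
  expect_equal(rv$verdict[rv$study_id == "IGF22"], "excluded_gh_response")
  expect_equal(rv$verdict[rv$study_id == "IGF08"], "excluded_gh_response")
  expect_equal(rv$verdict[rv$study_id == "IGF37"], "excluded_spont_both")
  expect_equal(rv$verdict[rv$study_id == "IGF50"], "excluded_spont_igf1")
  set.seed(37)
  for (rep in 1:3) {
    shuffled <- step6_review(rec[sample(nrow(rec)), ])
    expect_equal(shuffled$verdict[match(rv$study_id, shuffled$study_id)],
                 rv$verdict)
  }
  # exactly one verdict per reviewed patient
  expect_equal(nrow(rv), dplyr::n_distinct(rv$study_id))
  # evidence is non-empty for every excluded record
  expect_true(all(nchar(rv$evidence[rv$verdict != "spigfd_candidate"]) > 0))
})

test_that("a true-SPIGFD archetype is never excluded by the trajectory review", {
  # monotonically low IGF-1, persistently z <= -3, no GH therapy
  dates <- as.Date("2015-01-06") + round(seq(0, 48, by = 6) * 30.4375)
  ages <- 48 + seq(0, 48, by = 6)
  coh <- emr_cohort(
    patients = mk_patient("P1", birth = "2011-01-10"),
    observations = mk_height("P1", dates, height_at_z(ages, -3.6)),
    labs = mk_igf1("P1", dates, rep(25, length(dates))))
  cands <- tibble::tibble(patient_id = "P1", index_date = dates[1])
  recs <- build_review_records(coh, cands, ref, flat_igf1_ref(),
                               default_assay_calendar())
  rv <- step6_review(recs)
  expect_equal(rv$verdict, "spigfd_candidate")
})

test_that("the normalization summary covers only spontaneous normalizers", {
  recs <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    gh_treated = c(TRUE, FALSE, FALSE, FALSE),
    gh_clinical_response = c(TRUE, FALSE, FALSE, FALSE),
    gh_lab_response = c(FALSE, FALSE, FALSE, FALSE),
    spont_growth_norm = c(FALSE, FALSE, TRUE, FALSE),
    spont_igf1_norm = c(FALSE, TRUE, TRUE, FALSE),
    months_to_normalization = c(3, 10.8, 6.1, NA))
  rv <- step6_review(recs)
  ns <- normalization_summary(rv)
  expect_equal(ns$n, 2L)
  expect_equal(ns$median_months, (10.8 + 6.1) / 2)
  expect_equal(ns$range_months, c(6.1, 10.8))
  g <- glance(rv)
  expect_equal(g$n_spigfd_candidate, 1L)
  expect_equal(g$prevalence_pct, 25)
})
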