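#' Packaged study fixtures
#'
#' Two small fixtures accompany the package: the published screening-funnel
#' stage counts of the source cohort, and the published 11-record chart-review
#' table of children with potential SPIGFD (study id, clinical diagnosis, GH
#' treatment flag, treatment-response descriptor, spontaneous growth/IGF-1
#' normalization flags). They let the reporting arithmetic and the step-6
#' classifier be exercised against printed results without any patient data.
#'
#' @name fixtures
NULL

#' Published funnel stage counts
#'
#' Stage counts of the source cohort: 4863 children with short stature,
#' 233 with low IGF-1, 124 with both within one year, 30 with no
#' algorithm-detected secondary cause, and 11 entering the final trajectory
#' review after manual exclusion of residual secondary IGF-1 deficiency.
#'
#' @return tibble `step`, `label`, `n`.
#' @export
funnel_fixture <- function() {
  tibble(
    step = 1:5,
    label = c("short stature (height z <= -3.0)",
              "low IGF-1 (< 2.5th percentile)",
              "short stature within 1 year of low IGF-1",
              "no secondary cause (algorithm)",
              "entering trajectory review (manual screen)"),
    n = c(4863L, 233L, 124L, 30L, 11L))
}

#' Published chart-review case fixture
#'
#' The 11 reviewed records transcribed from the source study, with the
#' response descriptors parsed into the logical evidence flags that
#' [step6_review()] consumes: `gh_lab_response` is a "Good laboratory
#' response" (IGF-1 normalized on GH therapy), `gh_clinical_response` a good
#' clinical height response.
#'
#' @return tibble with `study_id`, `clinical_diagnosis`, raw descriptor
#'   columns, and parsed flags `gh_treated`, `gh_lab_response`,
#'   `gh_clinical_response`, `spont_growth_norm`, `spont_igf1_norm`.
#' @export
review_fixture <- function() {
  path <- system.file("extdata", "review_cases.tsv", package = "spigfd",
                      mustWork = TRUE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  x |>
    mutate(
      gh_treated = .data$gh_treatment == "Y",
      gh_lab_response = grepl("^Good laboratory", .data$gh_response),
      gh_clinical_response = grepl("and clinical response", .data$gh_response),
      spont_growth_norm = .data$spont_growth_normalization == "Y",
      spont_igf1_norm = .data$spont_igf1_normalization == "Y")
}
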