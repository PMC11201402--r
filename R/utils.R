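#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows distinct n rename
#'   slice_min slice_head row_number across all_of if_else first last pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm rnorm runif rlnorm median setNames
#' @importFrom utils head
NULL

# Days per month used to convert exact day differences to fractional months.
MONTH_DAYS <- 30.4375

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed clinical percentages are
#' conventionally rounded half-up (233/4863 renders as 4.8%). Used for all
#' reported percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.25, 1) # 0.3, where round(0.25, 1) is 0.2
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Age in months from exact day difference
#'
#' Converts day-resolution date pairs to fractional months using the mean
#' Gregorian month length (30.4375 days), the package's documented convention.
#'
#' @param birth_date,date `Date` vectors (recycled).
#' @return numeric months.
#' @export
age_months_at <- function(birth_date, date) {
  as.numeric(as.Date(date) - as.Date(birth_date)) / MONTH_DAYS
}

# Normalize ICD-10 codes/prefixes for matching: uppercase, dots stripped.
icd10_normalize <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

# Lexical ICD-10 shape: letter, two digits, optional alphanumeric suffix
# (dot optional before the suffix).
icd10_valid <- function(code) {
  grepl("^[A-Za-z][0-9]{2}(\\.?[0-9A-Za-z]{0,4})?$", trimws(code))
}

#' Match ICD-10 codes against prefix sets
#'
#' Matching is prefix-based after dot-stripping, so prefix "E03" matches
#' "E03.9"; code-set lists are customarily prefixes.
#'
#' @param codes character vector of ICD-10 codes.
#' @param prefixes character vector of ICD-10 prefixes.
#' @return logical vector, `TRUE` where a code starts with any prefix.
#' @export
icd10_matches <- function(codes, prefixes) {
  if (length(prefixes) == 0L || length(codes) == 0L) {
    return(rep(FALSE, length(codes)))
  }
  codes <- icd10_normalize(codes)
  prefixes <- icd10_normalize(prefixes)
  Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
}

# Seeded evaluation that restores the RNG state afterwards and pins the RNG
# algorithms so generated cohorts are reproducible across platforms.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Interval membership for exposure windows: start <= d <= end, end open-ended
# when missing. `starts`/`ends` are parallel vectors of one patient's intervals.
date_in_intervals <- function(d, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(d)))
  vapply(as.numeric(as.Date(d)), function(x) {
    any(x >= as.numeric(as.Date(starts)) &
          (is.na(ends) | x <= as.numeric(as.Date(ends))))
  }, logical(1))
}
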