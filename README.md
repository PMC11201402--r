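# spigfd

An R package implementing a six-step computable phenotype that screens
longitudinal electronic-medical-record (EMR) extracts for children with
**severe primary IGF-1 deficiency (SPIGFD)** — an ultra-rare short-stature
disorder in which serum insulin-like growth factor 1 (IGF-1) stays low despite
sufficient growth hormone (GH) and no secondary cause. Children with true
SPIGFD benefit from recombinant human IGF-1, but single low IGF-1 values are
common and usually transient, so case-finding needs anthropometry, stratified
laboratory reference bounds, diagnosis-code exclusions and longitudinal
trajectory review combined. The package is written for pediatric-endocrinology
and clinical-informatics groups who want to run (and re-parameterize) the
phenotype on their own EMR extracts, and for methodologists who want a fully
testable reference implementation.

## The algorithm

Anthropometry uses the LMS growth-reference parameterization: a measurement
*x* at a given sex and age converts to a standard-deviation score

    z = ((x/M)^L − 1) / (L·S)        for |L| > 1e−7
    z = ln(x/M) / S                  otherwise

against a pluggable reference table. The funnel then retains, in order:

1. children with any height-for-age **z ≤ −3.0**;
2. of those, children with ≥1 basal IGF-1 **below the 2.5th percentile** of
   the assay in effect on the collection date (stratified by sex and Tanner
   stage / bone age / chronological age, precedence in that order); the first
   low result is the index;
3. of those, children whose qualifying height lies **within ±365 days** of the
   index;
4. of those, children with **no secondary cause**: no ICD-10 code in the
   configured sets (malnutrition, hypothyroidism, GH deficiency /
   hypopituitarism, liver disease) and no BMI-for-age below the 5th
   percentile near the index;
5. children whose peak stimulated GH is below the analyzer-era threshold
   (5.4 ng/mL Dxl era, 7.4 ng/mL Roche era) are excluded as **GH-deficient**;
6. a trajectory review excludes children with a good clinical GH response
   (height gain > 0.5 SDS within 12 months on therapy), IGF-1 normalization on
   GH therapy, or spontaneous normalization of IGF-1 and/or growth. Survivors
   are **SPIGFD candidates**.

A seeded synthetic-EMR generator (`generate_cohort()`) produces cohorts with
ground-truth archetypes — normal stature, short-only, secondary-cause
confounders, constitutional-delay normalizers, GH responders and planted true
SPIGFD — so every stage is testable without patient data.

## Worked example

```r
library(spigfd)

sim <- generate_cohort(cohort_spec(n_patients = 200, seed = 42))
run <- run_pipeline(sim$cohort, sim$growth_reference, sim$igf1_reference)
run
#> SPIGFD screening run
#> Step 1 | short stature (height z <= threshold): 130 (100.0%)
#> Step 2 | low IGF-1 (< 2.5th percentile): 90 (69.2%)
#> Step 3 | short stature within the linkage window of low IGF-1: 90 (69.2%)
#> Step 4 | no secondary cause (candidate cases): 50 (38.5%)
#> Step 5 | entering trajectory review (GH-sufficient): 50 (38.5%)
#> Step 6 | SPIGFD candidates after review: 10 (7.7%)
#> SPIGFD candidate prevalence among reviewed: 20.0%
```

Of 200 simulated children, 130 ever measure at or below −3.0 height SDS, 90
of them also have a low IGF-1 linked within a year, secondary causes remove
40, and the trajectory review leaves exactly the 10 planted true-SPIGFD
archetypes (5% of the cohort) as candidates. `glance(run)` returns the stage
counts plus mean (SD) age, height and weight z at the index, follow-up span
and height-SDS change; `tidy(run)` returns the funnel table; `autoplot(run)`
draws it. Classifying the packaged 11-record published chart-review fixture:

```r
step6_review(review_fixture()) |> tidy()
#> # A tibble: 4 × 2
#>   verdict                  n
#>   <chr>                <int>
#> 1 spigfd_candidate         0
#> 2 excluded_gh_response     5
#> 3 excluded_spont_igf1      4
#> 4 excluded_spont_both      2
```

— five GH-related exclusions, four spontaneous IGF-1 normalizations, two
spontaneous normalizations of both growth and IGF-1, and no remaining
candidates (0% prevalence among the reviewed).

Real analyses plug in their own growth reference and IGF-1 package-insert
tables via `read_growth_reference()` / `read_igf1_reference()` (simple TSV
formats) and their own ICD-10 code sets via `run_config()`; the bundled
tables are synthetic and for testing only. A thin command-line front end
lives at `inst/cli/spigfd.R` (`run`, `simulate`, `fixtures`, `report`).

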