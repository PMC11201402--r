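---
title: "Methods: a computable phenotype for severe primary IGF-1 deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a computable phenotype for severe primary IGF-1 deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spigfd)
```

## The clinical problem

Severe primary IGF-1 deficiency (SPIGFD) is an ultra-rare cause of short
stature: serum insulin-like growth factor 1 (IGF-1) is persistently low even
though growth hormone (GH) secretion is sufficient, and no secondary
explanation (malnutrition, hypothyroidism, GH deficiency, liver disease,
chronic supraphysiologic glucocorticoids) accounts for it. It matters because
affected children respond to recombinant human IGF-1, and because a single low
IGF-1 value is diagnostically meaningless — constitutional-delay children
normalize spontaneously, typically within one to two years, and GH-treated
children normalize on therapy. A computable phenotype therefore has to combine
anthropometry, stratified laboratory reference bounds, diagnosis-code
exclusion logic and longitudinal trajectory review.

`spigfd` implements that phenotype as six sequential steps over flat EMR
extract tables:

1. **Short stature** — any height-for-age z-score at or below −3.0 SDS.
2. **Low IGF-1** — at least one basal IGF-1 strictly below the
   2.5th-percentile lower bound of the assay in use on the collection date,
   stratified by sex and Tanner stage, bone age, or chronological age; the
   *first* recorded low result becomes the patient's index.
3. **Temporal linkage** — a qualifying height within ±365 days of the index.
4. **Secondary-cause exclusion** — any ICD-10 code in the configured
   secondary-cause sets (visit diagnoses or problem list, any date), or a
   BMI-for-age below the 5th percentile near the index (malnutrition proxy).
5. **GH-deficiency screen** — peak stimulated GH (clonidine/arginine) below
   the analyzer-era threshold: 5.4 ng/mL (Dxl era) or 7.4 ng/mL (Roche era,
   from 2019-11-27). Untested children are indeterminate and stay under
   review.
6. **Trajectory review** — exclude children with a good clinical GH response
   (height gain > 0.5 SDS within 12 months on therapy), IGF-1 normalization on
   GH therapy, or spontaneous normalization of IGF-1 and/or growth. Survivors
   are SPIGFD candidates.

## The quantitative substrate: LMS z-scores

Growth references are supplied as LMS tables (skewness `L`, median `M`,
coefficient of variation `S` on a sex × age grid). A measurement `x` converts
to

$$ z = \frac{(x/M)^L - 1}{L\,S} \quad (|L| > 10^{-7}), \qquad
   z = \frac{\ln(x/M)}{S} \quad \text{otherwise,} $$

and the percentile is the standard-normal CDF of `z` times 100. Numerical
choices:

* **Log-branch tolerance** |L| < 1e−7 keeps the transform continuous across
  the L = 0 singularity; the two branches agree to better than 1e−6 SDS at
  the crossover (tested).
* **Linear interpolation** of `L`, `M`, `S` separately between grid ages —
  the convention of common growth-chart implementations, and analytically
  testable against a pre-densified grid.
* **No extrapolation**: ages outside the table raise an error (pipeline steps
  instead log and skip those observations). Silent extrapolation would
  corrupt thresholding exactly where it matters, at the ±3 SDS tails.
* **Age convention**: exact days since birth ÷ 30.4375. Chart data are
  day-resolution; a fixed divisor makes every age deterministic.
* z-scores are **not rounded** before thresholding; the −3.0 boundary is
  inclusive (`z ≤ −3.0` qualifies) because the operative step text of the
  algorithm uses the inclusive form, and the boundary is configurable.

Real national growth references and laboratory IGF-1 package inserts are
deliberately *plug-ins* (`read_growth_reference()`, `read_igf1_reference()`,
tab-separated): editions and lots differ by site, so the package bundles only
small synthetic tables with exactly known thresholds, keeping algorithm
correctness separable from reference-table fidelity.

## IGF-1 classification decisions

* **Assay calendar**: IDS-iSYS from November 2013, Liaison from October 2017;
  a boundary date belongs to the newer assay. The published switch is given at
  month granularity, so the package fixes 2017-10-01 (configurable). The GH
  analyzer switch is day-exact (2019-11-27).
* **Stratifier precedence** Tanner stage > bone age > chronological age. The
  source criteria say "and/or" without an order; puberty shifts IGF-1 norms
  far more than calendar age, so pubertal staging wins when available. A
  staging read is usable within 365 days of the lab date — a declared
  default, not a published value — and both precedence and recency are
  configurable. The stratifier actually applied is recorded on every result.
* **Strictness**: a value exactly at the 2.5th-percentile bound is *not* low;
  a peak GH exactly at 5.4/7.4 is *not* deficient. Ties at thresholds go to
  the non-pathological side everywhere.
* **Unclassifiable results** (no applicable reference entry) are flagged and
  treated as not-low rather than as errors, mirroring a chart-review posture
  of not excluding a child for a missing reference; every such event is
  visible in the classification table.
* **First-low tie-break**: same-date lows order by result id, making the
  index deterministic under permutation.

## Step-specific decisions

* **One-year window** (step 3): symmetric, inclusive, ±365 days; a 365-day
  gap links, a 366-day gap does not. Direction is not stated in the source
  criteria, and the window is configurable.
* **Secondary-cause codes** (step 4) count from *any* date and both sources,
  because problem lists are cumulative. The shipped prefix sets
  (malnutrition E40–E46, R63.4, R63.6; hypothyroidism E00–E03; GH deficiency
  E23.0; hypopituitarism E23; liver disease K70–K77) are editable defaults —
  institutional code lists vary and the original list is not reproducible
  from the available text.
* **BMI proxy**: heights and weights pair within a configurable window
  (default: same encounter date); the pair nearest the index date is
  evaluated against the 5th percentile (z < −1.6449). The source anchors this
  rule loosely in time, so the nearest-encounter choice is declared here.
* **Growth normalization** (step 6) has no published formula; the package
  rule is *return above −2.0 SDS after having been at or below −3.0*, or an
  off-treatment gain > 0.5 SDS within ≤366 days (the same velocity rule as
  the GH response, restricted to off-therapy pairs). Both thresholds are
  configurable and the rule is deliberately conservative: a child who merely
  drifts within the severe range never counts as normalized.
* **Verdict precedence**: GH-related exclusion (clinical response *or* IGF-1
  normalization on therapy) > spontaneous both > spontaneous IGF-1 only >
  spontaneous growth only > SPIGFD candidate. A record with a good laboratory
  response but a poor clinical response is still a GH-related exclusion —
  on-treatment IGF-1 normalization is an independent exclusion ground, and
  the published 11-record review table only sums to its three class counts
  under that reading. Growth-only spontaneous normalization is an extra
  verdict class: the algorithm text excludes on "IGF-1 and/or growth", so a
  growth-only normalizer cannot remain a candidate.
* **12-month window** for the GH response uses ≤366 days to absorb leap
  years.
* **Indeterminate GH status** (no stimulation test) never excludes: in the
  source cohort roughly half the reviewed children had no test yet remained
  under review.

## The synthetic-EMR generator

`generate_cohort()` emulates a pediatric tertiary-care screening population
with six archetypes and writes a ground-truth table alongside the bundle:

| archetype | share | construction | expected fate |
|---|---|---|---|
| normal stature | 0.35 | z ≈ N(0, 0.7), normal IGF-1 | screened out |
| short stature only | 0.20 | z in [−3.8, −3.2], normal IGF-1 | screened out |
| secondary cause | 0.20 | short + low IGF-1 + an exclusion code or BMI z ≈ −2.2 | excluded at step 4 |
| constitutional-delay normalizer | 0.10 | low IGF-1 until a sampled normalization time; half also recover height to −1.5 SDS | spontaneous-IGF-1 (or both) |
| GH responder | 0.10 | GH interval with on-treatment gain ≈ 1.4 SDS/year and IGF-1 normalizing on therapy | GH-related exclusion |
| true SPIGFD | 0.05 | z drifting slowly within about [−4.2, −3.3], all IGF-1 at ~55% of the bound, normal GH stimulation, no codes | SPIGFD candidate |

Defaults chosen once as field-plausible study conditions: 200 patients,
6-monthly visits (±10 days of jitter) over 5 years of follow-up — echoing the
source cohort's ~5-year mean follow-up — 0.3 cm height measurement noise, 5%
multiplicative IGF-1 noise, entry ages 24–150 months (so every visit stays
inside the bundled reference grid), and spontaneous normalization times drawn
log-normally with median 10.8 months truncated to [6.1, 24.1] months, the
published median and range. The truncation echoes the reported range; no
claim is made about the true distribution. All randomness is fixed by the
spec seed under pinned RNG algorithms (Mersenne-Twister / inversion /
rejection), so bundles are reproducible across platforms.

What the generator does *not* emulate: realistic ICD-10 co-occurrence,
demographic structure beyond age and sex, missing-data patterns, assay
drift within an era, or measurement error correlated within visits. Passing
the recovery harness therefore demonstrates that the *algorithm logic* is
correct under its stated assumptions — not that the phenotype has any
particular sensitivity on real charts, where data gaps (e.g. an IGF-1 never
drawn) dominate.

## Reporting conventions

Attrition percentages against the short-stature denominator are rendered to
one decimal with half-up rounding; within-subset shares to whole percent —
both formats appear in conventional cohort reporting, and both are emitted
(`pct_of_step1`, `share_of_prev`). Reports are pure functions of (bundle,
configuration): repeated runs produce byte-identical JSON. Every exclusion
carries the patient id, the rule that fired and its evidence, so each one can
be re-verified against the raw tables.

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(cohort_spec(n_patients = 200, seed = 42))
run <- run_pipeline(sim$cohort, sim$growth_reference, sim$igf1_reference)
run           # prints the funnel
glance(run)   # one-row summary with candidate prevalence
autoplot(run) # funnel figure

# classify the packaged 11-record published review table
step6_review(review_fixture()) |> tidy()
```

## Problem sizes and known limitations

The test suite exercises the full pipeline on 200-patient cohorts across 20
seeds (the recovery harness) and on 40–80-patient cohorts elsewhere; the
brute-force oracles run on 50-patient cohorts. These sizes were chosen as the
smallest at which every archetype appears in realistic numbers.

Limitations: step 3 requires the *qualifying* (≤ −3.0 SDS) height within the
window, not any height — the source text reads either way and the choice is
configurable; GH sufficiency accepts a single adequate peak ("clonidine
and/or arginine"), not necessarily failure of both agents; the growth
normalization rule is an artifact decision; and the funnel's absolute counts
from the source cohort are reproducible only as packaged fixture arithmetic,
since the underlying records are not public.
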