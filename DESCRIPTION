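Package: spigfd
Title: EMR Case-Finding Pipeline for Severe Primary IGF-1 Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-step computable-phenotype pipeline that screens longitudinal
    electronic medical record extracts for children with severe primary
    insulin-like growth factor 1 (IGF-1) deficiency (SPIGFD): LMS growth-reference
    z-scores, assay- and stratifier-aware IGF-1 classification against 2.5th
    percentile reference bounds, temporal linkage of short stature to low IGF-1,
    ICD-10 code-set exclusion of secondary IGF-1 deficiency, growth-category
    labelling, growth-hormone stimulation and treatment-response review, and
    spontaneous-normalization detection. Includes a seeded synthetic-EMR
    generator with ground-truth archetypes so every stage is testable without
    patient data, plus funnel reporting with attrition percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
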