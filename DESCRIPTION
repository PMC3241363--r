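Package: rametab
Title: OPLS-DA Diagnostic Modelling of Serum Metabolite Profiles in Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for diagnosing rheumatoid arthritis from
    semiquantitative serum metabolite profiles. Implements orthogonal
    projections to latent structures discriminant analysis (OPLS-DA) with a
    single-response NIPALS algorithm, stratified sevenfold cross-validated
    diagnosis with sensitivity/specificity/Q2 reporting, external-cohort
    validation through a shared identified-metabolite subset, metabolite
    ranking by correlation loading p(corr), control-referenced standard-score
    heat-map matrices, and per-metabolite pooled-variance t-test tables.
    Includes a synthetic serum-metabolome cohort generator with planted
    group effects and rank-1 orthogonal nuisance variation so that the whole
    workflow is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
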