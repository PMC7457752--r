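Package: oncovalue
Title: Clinical-Benefit Scoring of Oncology Trials with the ASCO Value
    Framework and the ESMO Magnitude of Clinical Benefit Scale
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scoring engines for the two major oncology clinical-benefit
    value frameworks: the 2016 update of the American Society of Clinical
    Oncology Value Framework (ASCO-VF), which produces a continuous Net
    Health Benefit (NHB) score from the hazard ratio, grade 3-4 toxicity
    burden and bonus points for durable survival, palliation, quality of
    life and treatment-free interval; and the European Society for Medical
    Oncology Magnitude of Clinical Benefit Scale (ESMO-MCBS) v1.1, which
    grades randomized trials 1-5 (non-curative) or A-C (curative) from the
    lower confidence limit of the hazard ratio, median-survival gains,
    landmark-survival gains and quality-of-life/toxicity adjustments.
    Includes a validated trial-arm data model with CSV/JSON serialization,
    packaged per-arm data for the 18 FDA-approved immune-checkpoint-
    inhibitor indications supported by randomized trials (initial and
    updated assessments), cohort summaries and initial-versus-updated
    comparisons, and a seeded mixture-cure trial simulator for exercising
    every scoring rule on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
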