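Package: tkacea
Title: Cost-Effectiveness of Total Knee Arthroplasty by Personality Trait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-level cost-effectiveness analysis of total knee
    arthroplasty (TKA) stratified by Eysenck personality quadrant. Scores
    48-item Eysenck Personality Questionnaire (EPQ) sheets into the four
    classical temperaments (choleric, sanguine, melancholic, phlegmatic),
    maps WOMAC osteoarthritis totals to health-state utilities, simulates
    discounted quality-adjusted life years (QALYs) gained with a
    prosthesis-revision adjustment, and computes marginal
    cost-effectiveness ratios (MCER, $/QALY) with deterministic one-way
    sensitivity analysis. Includes a seeded synthetic-cohort generator
    calibrated to published summary tables, cohort statistics (chi-square,
    one-way ANOVA with Tukey HSD, logistic regression on MCER, sample-size
    and reliability calculators), input validation, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
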