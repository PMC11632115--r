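Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII extracts. Reads and writes
    the "$"-delimited FAERS tables, deduplicates case reports, selects
    primary-suspect drug reports with drug-name standardization, applies
    minimum report-count filtering of MedDRA preferred terms and maps them to
    system organ classes, and computes four disproportionality statistics for
    each drug-event pair against the database background: the reporting odds
    ratio (ROR) and proportional reporting ratio (PRR) with Wald confidence
    intervals and chi-squared tests, the Bayesian confidence propagation
    neural network information component (IC with IC025), and the multi-item
    gamma Poisson shrinker (MGPS) empirical-Bayes geometric mean (EBGM with
    EBGM05) under a maximum-likelihood two-component gamma mixture prior.
    Also provides reporting-cohort descriptive summaries, time-to-onset
    analysis, a seeded synthetic FAERS generator with planted signals for
    validation, and an end-to-end pipeline with an attrition manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
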