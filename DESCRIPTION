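Package: pvsignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pharmacovigilance signal detection on FDA Adverse Event Reporting
    System (FAERS) style quarterly ASCII data: ingestion of the
    DEMO/DRUG/REAC/OUTC/THER tables and deleted-report lists, FDA-recommended
    case deduplication, primary-suspect cohort extraction for a target drug,
    descriptive constituent-ratio summaries, and four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    chi-squared, the BCPNN information component, and a closed-form empirical
    Bayes geometric mean) computed from 2x2 contingency tables at the MedDRA
    Preferred Term and System Organ Class levels. A synthetic spontaneous
    report generator with injected reporting-rate signals supports
    end-to-end validation without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
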