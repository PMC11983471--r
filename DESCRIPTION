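Package: pvsignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pharmacovigilance analysis pipeline for spontaneous
    adverse-event reports in the FDA Adverse Event Reporting System (FAERS)
    quarterly ASCII format. Reads the dollar-delimited DEMO/DRUG/REAC/OUTC
    tables, collapses duplicate case submissions to the most recent report
    per case using the CASEID/FDA_DT/PRIMARYID rule, extracts case sets for
    a target MedDRA preferred term, normalizes verbatim drug names through a
    user-supplied dictionary, computes per-drug reporting odds ratios with
    Woolf 95% confidence intervals and signal flags, and produces
    demographic and outcome stratifications. A synthetic report generator
    with planted drug-event odds ratios, injected duplicate submissions and
    a ground-truth manifest supports end-to-end validation without any
    database download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
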