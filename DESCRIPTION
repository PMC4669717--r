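Package: sigreverse
Title: Signature-Reversal Drug Repositioning with Connectivity-Map-Style
    Scoring
Version: 0.1.0
Authors@R:
    person("sigreverse", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An in-silico drug repositioning screen: extracts up/down probe
    signatures from case/control expression matrices by pooled t-test and
    fold-change thresholds, scores them against a compendium of
    drug-treatment rank profiles with the Kolmogorov-Smirnov tag enrichment
    statistic, retains drugs whose profiles reverse the disease signature
    (negative enrichment, p < 0.05) and fuses hits across cohorts. Includes
    a synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads.
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
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
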