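Package: cmapscreen
Title: Signature-Based Connectivity Screening of Drug Perturbation Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico drug screen built on the classic Connectivity Map
    (CMap) statistic: two-sided Kolmogorov-Smirnov enrichment of a signed
    transcriptomic query signature (up- and down-regulated gene tag lists)
    against a compendium of per-instance drug-perturbation gene rankings.
    Instance-level connectivity scores are scaled onto [-1, +1], aggregated
    per compound, and annotated with a permutation p-value, Benjamini-Hochberg
    FDR, instance count, non-null ratio, and a specificity score derived from
    background gene-set collections; a composite reliability score ranks
    compounds. Includes readers and writers for GRP, GMT, GCT 1.2 and TSV rank
    matrices, a synthetic compendium generator with planted mimic and
    anti-mimic compounds for calibration and recovery testing, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
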