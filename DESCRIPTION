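Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for FAERS-style
    spontaneous adverse event report data. Reads the quarterly
    dollar-delimited ASCII tables (DEMO, DRUG, REAC, OUTC), deduplicates
    case versions by CASEID/FDA_DT/PRIMARYID, restricts to primary-suspect
    drugs, normalizes drug names against an editable synonym dictionary,
    maps reaction preferred terms through a MedDRA-like PT/HLT/HLGT/SOC
    hierarchy, and screens drug-event pairs with four disproportionality
    statistics: the reporting odds ratio (ROR), the proportional reporting
    ratio (PRR) with Yates chi-square, the Bayesian confidence propagation
    neural network information component (IC), and the empirical Bayes
    geometric mean (EBGM) from DuMouchel's multi-item gamma-Poisson
    shrinker, with Fisher exact p-values and Bonferroni correction.
    Includes sex and age subgroup analysis, descriptive tables, system
    organ class summaries, and a seeded synthetic FAERS-format data
    generator with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
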