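Package: fewqc
Title: Water Quality Criteria and Ecological Risk Assessment for Ferric Iron
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives short-term and long-term freshwater quality criteria for
    ferric iron from curated ecotoxicity records using three standard methods:
    the assessment factor method, the US EPA toxicity percentage ranking
    procedure (final acute value, criteria maximum and continuous
    concentrations), and species sensitivity distributions fitted to ranked
    species geometric means with hazard-concentration (HC5) inversion. The
    derived criteria feed a dual acute/chronic risk-quotient ecological risk
    assessment of surface-water exposure records, with risk classification and
    basin-level aggregation. Seeded generators produce synthetic exposure and
    toxicity datasets for method validation. Ships a curated reference table
    of 47 ferric-iron toxicity records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
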