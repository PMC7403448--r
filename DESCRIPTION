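Package: cernasig
Title: Gene-Directed ceRNA Network Inference and lncRNA Prognostic
    Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds driver-gene-directed competing endogenous RNA (ceRNA)
    networks from paired expression profiles and validated miRNA-target
    maps, and derives multivariate Cox lncRNA risk signatures from them:
    correlation-gated triple identification, univariate Cox screening,
    bidirectional stepwise selection by AIC, linear risk scoring with a
    training-median cutoff, Kaplan-Meier / log-rank evaluation on held-out
    cohorts, chemotherapy-response association analyses, and hypergeometric
    over-representation analysis of co-expressed mRNAs. Includes a
    synthetic-cohort generator with planted ceRNA structure and planted
    proportional-hazards effects so the whole workflow is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
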