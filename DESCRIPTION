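Package: femscreen
Title: Endosymbiont Feminization Candidate Gene Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a comparative-genomics and
    expression-profiling screen for Wolbachia feminization candidate genes in
    terrestrial isopods. Provides qPCR amplification-curve processing and
    endosymbiont DNA enrichment accounting, exact pairwise protein alignment
    with ortholog clustering and core-genome computation, an ordered in-silico
    candidate filter cascade with a full audit trail, efficiency-corrected
    relative expression calibrated to a developmental stage with
    BestKeeper-style reference-gene selection, lagged cross-correlation of
    developmental expression profiles between hosts, and f-element copy
    mapping with an exact enrichment test. A synthetic-data module generates
    all pipeline inputs with planted truth, including a preset reproducing the
    published candidate funnel end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
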