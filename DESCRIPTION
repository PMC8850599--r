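Package: triadscreen
Title: Screening and Validation Analytics for lncRNA-miRNA-mRNA ceRNA Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for competing-endogenous-RNA (ceRNA) triad
    discovery and validation in Parkinson disease and similar case-control
    designs. Implements a seven-stage knowledge-base screening cascade that
    selects lncRNA-miRNA-mRNA triads with a full per-stage audit trail;
    comparative-CT (delta-delta-Ct) qRT-PCR relative quantification with an
    adaptive parametric/nonparametric group-comparison engine and ROC
    biomarker evaluation; a miRNA-centric regulatory-network builder with
    SIF/GraphML export; canonical miRNA seed-site scanning with wild-type /
    mutant construct verification and dual-luciferase reporter analytics;
    and synthetic-data generators with planted ground truth for every input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
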