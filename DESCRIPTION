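Package: sigmr
Title: Drug Signature Connectivity Scoring and Summary-Data Mendelian
    Randomization
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-armed analysis toolkit for investigating shared
    pharmacology between drug classes from transcriptomic perturbation
    signatures and for testing causal effects of drug-target gene
    expression on outcome traits.  The transcriptomic arm implements
    Connectivity-Map-style signature matching: query construction from
    top up- and down-regulated landmark genes, weighted Kolmogorov-
    Smirnov enrichment, weighted two-sided connectivity scores (WTCS),
    sign-stratified normalization (NCS), Tau percentiles against a
    touchstone reference set, drug-class enrichment testing, directional
    concordance of perturbed genes, and hypergeometric term enrichment
    over an ontology DAG.  The genetic arm implements summary-data
    Mendelian randomization (SMR) with eQTL instrument selection, allele
    harmonization, the HEIDI heterogeneity test, and multiple-testing
    thresholds.  A synthetic-data generator with known ground truth
    (planted compound classes; simulated genotype cohorts under causal,
    null and linkage scenarios) makes every stage testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
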