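Package: respcard
Title: Integration of Ex Vivo Drug Response and Tumor Genomics for
    Per-Patient Response Cards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating ex vivo small-molecule inhibitor screens
    of patient-derived tumor cell cultures with genomic characterization of
    the same tumors. Implements dose-response processing of plate viability
    data into harmonized, QC-flagged area-under-the-curve (AUC) values;
    filtering of drug-target evidence into a high-confidence binary target
    matrix; a per-gene drug-sensitivity score (sum of per-drug AUC Z-scores
    over the drugs targeting the gene) with a drug-label permutation test;
    random-walk-with-restarts network propagation of significant genes over
    a confidence-filtered interaction network with degree-preserving rewired
    network (RDPN) empirical p-values; gene-level copy-number calling,
    somatic variant filtering, expression/protein concordance classification
    and Jaccard-based cell-line matching; nearest-centroid expression
    subtype calling with an indeterminacy rule; paired tests of drug
    combinations against their best single agent; and assembly of
    per-patient Response Cards joining all of the above. A synthetic-data
    module generates every input with known planted structure so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
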