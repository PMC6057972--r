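Package: tmetools
Title: Tumor-Microenvironment Repertoire and Transcriptome Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the immune tumor microenvironment of a mouse
    B-cell leukemia model under interferon-alpha gene therapy. Implements
    TCR-beta repertoire statistics (clonality as one minus Pielou's evenness,
    similarity as one minus Bray-Curtis distance to the timepoint mean), a
    single-cell RNA-seq pipeline (UMI quality control, log-normalization,
    covariate-regression scaling, binned-dispersion variable-gene selection,
    PCA, shared-nearest-neighbor graph clustering, cluster-enrichment log
    fold changes with expression-fraction filters, reference-derived cell-type
    gene signatures, minimum-spanning-tree sub-cluster trajectories), bulk
    RNA-seq preprocessing filters (CPM/RPKM, expression and differential
    expression thresholds), and negative-binomial synthetic-data generators
    that emulate the statistical structure of all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    limma,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
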