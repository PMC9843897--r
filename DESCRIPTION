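Package: convexpr
Title: Cross-Species Convergent Gene Expression Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a cross-species comparative
    transcriptomics workflow for detecting convergent gene expression in
    ecologically convergent lineages (e.g. the two bamboo-eating panda
    species among carnivorans). Starting from per-species gene-level count
    matrices and pairwise protein homology hit tables, the package selects
    longest-isoform representatives, derives 1:1 single-copy orthologues by
    reciprocal best hits, normalizes expression with gene-length-corrected
    TMM (GeTMM), performs negative-binomial exact-test differential
    expression per species pair with Benjamini-Hochberg adjustment, calls
    direction-consistent convergent genes shared by two focal species
    against every background species, and adds descriptive statistics
    (PCA, Spearman clustering, delta-delta-Ct), hypergeometric
    over-representation analysis, and promoter methylation scoring from
    cytosine reports. A synthetic-data generator with planted convergent
    genes provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
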