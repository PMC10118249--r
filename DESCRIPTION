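Package: MicrobeClubs
Title: Co-Occurrence Networks and Social/Rival Clubs in Lower-Airway Microbiomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of 16S OTU count tables from lower-respiratory-tract
    (bronchoalveolar lavage) cohorts: name-based contaminant removal, total-sum
    scaling, group-wise prevalence filtering, alpha diversity (Chao1, inverse
    Simpson, Faith's phylogenetic diversity), phylogenetic beta diversity
    (unweighted and weighted UniFrac) with principal coordinate analysis,
    PERMANOVA and multivariate dispersion, compositional correlation inference
    from log-ratio variances (SparCC-style, with Dirichlet resampling and
    permutation pseudo p-values), co-occurrence network construction, Markov
    clustering of the positive-association subgraph into microbial "social
    clubs", and detection of negatively associated "rival clubs". Includes a
    logistic-normal multinomial simulator with planted club/rivalry structure
    for end-to-end validation, and a configuration-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    phyloseq,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'synthetic.R'
    'preprocess.R'
    'diversity.R'
    'tree-metrics.R'
    'ordination.R'
    'sparcc.R'
    'clubs.R'
    'pipeline.R'
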