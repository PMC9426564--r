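Package: coamag
Title: Distance-Guided Coassembly Planning and MAG Evaluation for
    Shotgun Metagenomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the computational core of a genome-resolved
    metagenomics workflow: k-mer abundance profiles and
    abundance-weighted Jaccard (and Bray-Curtis) distances between
    metagenomes, unsupervised selection of coassembly sample sets by
    Ward hierarchical clustering with a silhouette-scored sweep over
    all cut levels, expansion of the four assembly-binning strategies
    (single/coassembly crossed with single/cobinning) into executable
    plans, per-contig depth tables in the MetaBAT2 dialect, genome
    breadth-of-coverage detection with prevalence-abundance summaries,
    CheckM-style quality classification of genome bins, and
    dereplication of metagenome-assembled genomes at species and
    strain average-nucleotide-identity thresholds using a windowed
    k-mer containment estimator. A deterministic synthetic-community
    generator (log-normal abundances, planted sample groups,
    controlled-divergence genome pairs) makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    igraph,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Clustering, Sequencing, Microbiome
RoxygenNote: 7.3.3
Collate:
    'coamag-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'RcppExports.R'
    'io.R'
    'kmer.R'
    'clustering.R'
    'strategy.R'
    'coverage.R'
    'quality.R'
    'synthetic.R'
    'pipeline.R'
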