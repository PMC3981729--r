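Package: dartpop
Title: Population Structure, Diversity and Linkage Disequilibrium for
    Dominant Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of dominant (presence/absence) biallelic marker
    panels such as DArT score sheets from selfing crop collections.
    Provides a SummarizedExperiment-based container for genotype by
    marker call matrices with genetic-map annotation, a Gibbs sampler
    for the Bayesian admixture model on haploid-scored markers with
    Evanno delta-K model selection, LD-based marker pruning, Jaccard
    distance and principal coordinate/component ordination with
    loading-based marker detection, AMOVA variance partitioning with
    permutation Phi-statistics, gene-diversity and marker-panel summary
    statistics, and an intra-chromosomal r2 linkage-disequilibrium decay
    estimator based on loess smoothing against an unlinked-pair
    background threshold. A seedable generator for synthetic dominant
    marker panels with Balding-Nichols differentiation and
    distance-dependent LD supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
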