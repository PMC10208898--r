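Package: PopGenFlow
Title: Divergence, Gene Flow and Selection Scans for Resequenced Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated population-genomics toolkit for closely related
    plant lineages sampled by whole-genome resequencing. Implements variant
    filtering, LD pruning and SNP effect classification downstream of a
    multi-sample VCF; windowed nucleotide diversity, Weir-Cockerham FST,
    ln pi-ratio and LD decay; Patterson's D and f4-ratio introgression tests
    with block-jackknife significance; folded site-frequency-spectrum
    demographic model fitting over five three-population scenario families
    with AIC model selection and physical-unit conversion; a cross-population
    composite-likelihood sweep scan with empirical top-quantile three-metric
    intersection calling; Schoener's D and Hellinger's I niche-overlap
    statistics with a permutation identity test; and a seeded structured
    coalescent generator producing every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
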