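Package: SweepDemes
Title: Selective-Sweep Scanning and Site-Frequency-Spectrum Demography for
    Resequencing Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-variant-calling population genomics for multi-population
    resequencing studies of domestication. Implements hard-filter and
    cluster/depth variant QC, sliding-window nucleotide diversity and
    Weir-Cockerham FST with joint outlier calling of selective sweeps,
    discovery of group-diagnostic fixed variants, folded joint
    site-frequency spectra with hypergeometric projection, composite-
    likelihood comparison of alternative domestication scenarios by AIC
    with real-unit parameter scaling and bootstrap intervals, and a
    structured-coalescent cohort simulator with sweep and diagnostic-locus
    injection that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    vcfR,
    ape,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, Coverage, VariantAnnotation, Sequencing
RoxygenNote: 7.3.3
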