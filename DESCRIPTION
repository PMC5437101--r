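Package: maizedemog
Title: Joint-SFS Demographic Inference and IBD Characterization for the
    Tropical-Temperate Maize Split
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model the divergence of temperate from tropical maize
    from a joint site-frequency spectrum: explicit two-population demographic
    timelines (domestication bottleneck, founder event, post-split linear
    decline, gene flow), a Monte Carlo structured-coalescent engine for
    expected spectra with an exact small-sample Markov-chain oracle, Poisson
    composite-likelihood fitting with profiled theta, nested likelihood-ratio
    tests, AIC and parametric bootstrap, conversion between coalescent-scaled
    and physical units, plus the accompanying population characterization
    (windowed Weir-Cockerham Fst, population-specific SNPs, LD decay and
    pruning, kinship filtering) and identity-by-descent segment
    post-processing (genetic-map interpolation, multi-run consensus, sharing
    summaries, hotspot windows, permutation overlap tests). A synthetic-data
    module generates every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    vcfR,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
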