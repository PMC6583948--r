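Package: SloanFit
Title: Neutral Community Model Fitting and Simulation for Host-Associated
    Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess how consistent host-associated (and
    environmental) microbial community composition is with neutral
    community assembly. Implements the Sloan neutral community model for
    large microbial populations: rarefaction of OTU count tables,
    calibration of the immigration parameter m against the observed
    occurrence-frequency versus mean-relative-abundance relationship,
    goodness-of-fit (R squared) and AIC comparison with a binomial
    random-sampling model, exact binomial prediction bands for calling
    over- and under-represented taxa, bootstrap confidence intervals, and
    an individual-based death-birth-immigration simulator of local
    communities coupled to a common source pool, including matched
    neutral benchmarks, subsampling and read-depth sensitivity curves,
    and time-course experiments on transient (non-equilibrium)
    communities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Microbiome, Metagenomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
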