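Package: mitodemes
Title: Demographic Inference and Dating for Serially Sampled Mitogenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the demographic history of a region from
    ancient and modern complete mitochondrial genomes. Provides a structured
    coalescent simulator with serial (ancient) sampling, epoch-wise deme sizes,
    backward migration matrices and population-replacement events; a library of
    continuity/discontinuity demographic models for an eleven-group
    ancient-plus-modern sampling design; haploid summary statistics (haplotype
    number and diversity, segregating sites, Tajima's D, pairwise FST and
    between-population differences) computed identically on observed and
    simulated alignments; approximate Bayesian computation model choice with
    random-forest classifiers, linear discriminant axes, out-of-bag error and
    posterior probability estimation; rho-statistic founder-age dating with a
    recalibration step that restores the mutations ancient tips never had time
    to accumulate; and exploratory structure analyses (FST matrices,
    multidimensional scaling, correspondence analysis, chi-square tests).
    A synthetic-data generator emulates an eleven-group ancient-plus-modern
    mitogenome study design so that every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    ranger
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
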