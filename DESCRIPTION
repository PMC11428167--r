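Package: watersig
Title: Microbiome Signatures That Discriminate Potable and Nonpotable Waters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discriminating water types (conventional
    potable, potable reuse, nonpotable reuse) from 16S rRNA gene feature tables.
    Implements blank-based prevalence decontamination, taxonomy-level collapsing,
    alpha and beta diversity with homogeneity-gated permutation statistics
    (ANOSIM, Betadisper, sequential PERMANOVA), a frequency-of-detection
    core/discriminatory classifier, an ANCOM-style differential-abundance test
    with centered-log-ratio fold changes, and a cross-method consensus that names
    signature taxa.  A Dirichlet-multinomial synthetic community generator with
    known ground truth drives testing of every downstream stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    vegan,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
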