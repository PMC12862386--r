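Package: rbpsuite
Title: Crosslink Peak Post-Processing and Companion Assays for RNA-Binding Protein Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream computational analyses of
    an RNA-binding-protein (RBP) multi-omic study: iCLIP crosslink-site post-processing
    (isotype-control subtraction, replicate merging, a within-gene permutation peak
    scorer with empirical FDR, biotype annotation, splice-junction metaprofiles),
    intron-binding analysis with a length-weighted random intron control and ANOVA on
    log intron lengths, an abundance-binned resampling null with empirical P-value for
    the overlap between differentially bound and differentially abundant genes,
    skipped-exon filtering and a logistic model associating a splicing-change metric
    with nearby binding, co-immunoprecipitation interactor classification (presence
    classes, asymmetric MinProb/kNN imputation, moderated testing), and membrane versus
    whole-cell intensity quantification from label masks. A synthetic-data module
    generates every input with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    jsonlite,
    yaml,
    withr,
    tiff,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    stringr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
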