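Package: seloop
Title: Super-Enhancers, Broad H3K4me3 Domains, and Their Loop-Mediated
    Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for connecting cis-regulatory
    elements to their target genes through chromatin interactions.
    Stitches H3K27ac peaks into enhancer candidates and separates
    super-enhancers from typical enhancers with the ROSE-style tangent
    cutoff on the ranked signal curve; ranks trimmed H3K4me3 gapped
    peaks by length to call broad domains; classifies elements as
    promoter-proximal or distal; intersects replicate ChIA-PET loop
    sets and assigns loop-mediated target genes; computes entropy-based
    cell-type specificity of CAGE cluster expression across facets;
    merges elements into a SE/BD region taxonomy and tests gene-set
    enrichment with Fisher's exact test, Holm-Sidak correction, and
    housekeeping-gene subsampling controls. Ships a deterministic
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
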