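Package: methdiv
Title: Population-Scale DNA Methylation Divergence via Jensen-Shannon Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scans of per-cytosine Jensen-Shannon divergence (JSD)
    and weighted methylation level (MET) across populations of bisulfite-
    sequencing methylomes, using the coverage-weighted plug-in entropy
    estimator. Classifies cytosines in the (MET, JSD) phase plane into low-,
    high-, medium-methylated and metastable types, and provides the downstream
    genomic statistics built on the scan: binned chromosome tracks, Spearman
    clustering of binned signals, metagene profiles with fixed flanks,
    metastable-gene selection, relative-distance spatial association, and
    randomization tests for structural-domain contrasts and gene-to-element
    proximity. Includes a synthetic methylome-population generator with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
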