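Package: creclass
Title: Rule-Based Classification of Cis-Regulatory Elements from Epigenomic Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labels chromatin-accessible or CTCF-bound genomic regions as
    Promoter, Enhancer, CTCF, Promoter/CTCF, Enhancer/CTCF or Not assigned
    using a deterministic two-phase rule engine over depth-normalized signal
    from H3K4me1, H3K4me3 and H3K27ac histone ChIP-seq and CTCF ChIP-seq.
    Includes per-region signal quantification from aligned reads (area under
    the coverage curve, counts-per-million normalized), within-region rank
    transformation, blacklist filtering, strand-aware distance to
    transcription start sites, variant-to-element intersection, coverage
    metaplot matrices, and a fully synthetic fixture generator with planted
    regulatory archetypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    BiocGenerics,
    stats,
    tools,
    utils,
    parallel,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
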