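Package: meiutr
Title: Discovery of Meiosis-Specific UTR Isoforms and URS1 Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates meiosis-specific 5' and 3' UTR extensions (mUTRs) of
    constitutively expressed yeast genes from segmented tiling-array expression
    data, and tests whether the Ume6-bound URS1 regulatory motif is enriched in
    their upstream regions. Provides the full segment-filtering and calling
    procedure (sporulation-specific expression, gene assignment by proximity to
    the TSS or terminator, decorrelation from the cognate ORF with
    Benjamini-Hochberg control), an information-weighted position weight matrix
    engine with core and matrix score similarity thresholds, permutation and
    exact count-based motif enrichment against cognate-promoter backgrounds,
    isoform length and expression-timing statistics, ChIP/qPCR quantification
    helpers, and a synthetic-data generator that emulates the mitotic, starving
    and sporulating sample design with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
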