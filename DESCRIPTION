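Package: acetatlas
Title: Differential Histone Acetylation Atlases and Consensus Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds non-redundant atlases of fixed-width, summit-centered
    candidate regulatory regions from histone acetylation (H3K9ac) ChIP-seq
    tags, scores the regions across samples as library-normalized extended-read
    counts, tests them for differential acetylation between condition groups
    with a Bayesian-regularized t-statistic, and detects over- or
    under-represented transcription factor consensus motifs in the variable
    regions with a bootstrap Z-score. Also implements the expression-side set
    logic for progression time courses (detection filtering, per-transition
    moderated differential expression, non-redundant unions and
    direction-matched intersections) and a synthetic-data generator with
    planted ground truth for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    MASS,
    methods,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
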