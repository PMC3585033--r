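Package: agescreen
Title: Screening Transcriptional Regulators of Aging from ChIP-Seq and
    Tag RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a screen for transcriptional
    regulators of aging in C. elegans. Binding sites from a multi-factor
    ChIP-seq compendium are filtered to factor-specific sites (removing
    promiscuously co-bound HOT regions), assigned to genes by peak summit
    position, and tested for overlap enrichment with age-regulated gene
    sets. Differential expression of replicated 3'-tag RNA-seq counts is
    called with a rank-products statistic and permutation-derived E-values
    and percent-false-positive rates. Binding-site sequence composition is
    screened for enriched k-mers in peak cores against flanking-sequence
    and Fisher-Yates-shuffled controls, and coordinate expression shifts
    of tissue gene sets are quantified with mean-centered fold-changes and
    Kolmogorov-Smirnov statistics. Negative-binomial count and synthetic
    genome/peak generators with recorded ground truth make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
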