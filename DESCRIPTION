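Package: coipop
Title: Population Structure and Thermal-Niche Analysis of COI Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cryptic invasions with mitochondrial COI
    barcode data: haplotype collapsing with ambiguity masking, Kimura
    2-parameter and net between-clade divergences, diversity indices and
    Tajima's D with a conditional-coalescent null distribution, hierarchical
    analysis of molecular variance (AMOVA) with permutation tests,
    median-joining haplotype networks with a statistical-parsimony connection
    limit, clade-wise sea-surface-temperature medians with bootstrap
    confidence intervals, rank-based partial Mantel tests of clade occurrence
    against temperature corrected for spatial distance, and zooid
    morphometric ANCOVA and regression. Includes a synthetic-data generator
    emulating deeply diverged clades distributed along a temperature
    gradient, so the whole pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
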