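Package: delhot
Title: Trio-Based Discovery of Rare Deletion Hotspots from SNP Array Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for mapping hotspots of large rare heterozygous
    deletions from SNP-array intensity data in parent-parent-child trios.
    Provides a synthetic trio-cohort generator with ground-truth deletions
    (hotspot-clustered spatial intensity, lognormal lengths, Mendelian
    transmission, de novo events), a rule-based deletion caller on LogR
    ratio tracks (minimum run of contiguous low-intensity SNPs), two-round
    parent/child cross-verification with targeted rescue and sensitivity
    estimation, rarity and independence filtering of events, a fixed-bin
    Poisson enrichment scan that calls deletion hotspots, and calculators
    for per-generation per-chromosome deletion rates, deletion length
    statistics and exon-overlap annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    BiocGenerics,
    GenomicRanges,
    methods,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
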