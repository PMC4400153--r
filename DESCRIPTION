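Package: islandswap
Title: Selective Introgression of X-Chromosome Divergence Islands:
    Simulation, Pool-Seq FST Scans and Mating Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genomic islands of divergence between the
    sibling mosquito taxa Anopheles coluzzii and Anopheles gambiae s.s.
    (the 'M' and 'S' molecular forms). Provides a forward-genetic simulator
    of marker-assisted backcross introgression of the pericentromeric
    X-chromosome island with ancestry-block tracking and pericentromeric
    recombination suppression; pooled-sequencing allele-frequency tables
    with binomial depth sampling on a ploidy grid; per-site FST scans
    (1 - Hs/Ht) with spline smoothing and introgressed-segment calling;
    codon-level annotation of fixed differences between pools with
    field-population conservation filtering; and likelihood-ratio (G) and
    Pearson goodness-of-fit statistics for assortative-mating assays,
    Mendelian ratios and Hardy-Weinberg expectations.
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
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
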