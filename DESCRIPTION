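Package: chrompool
Title: Scaffold Binning from Metaphase Chromosome-Pool Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns genome assembly scaffolds to chromosomes from dilution
    pools of metaphase chromosomes sequenced in barcoded wells. Provides
    read-count tabulation and depth/coverage normalization of per-well
    alignments, correlation-based K-means clustering of scaffold well
    profiles with elbow (within-cluster sum of squares knee) selection of
    the chromosome number, deduction of the binary chromosome-by-well
    occupancy configuration, per-chromosome meta-scaffold summaries (N50),
    a seeded simulator of pool experiments with known truth, and the
    quantitative design calculus of dilution-pool sequencing (repeat
    collision probability per well, majority-vote consensus error rate,
    fold coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    mclust,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
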