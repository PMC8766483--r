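Package: phagenet
Title: Structure and Sequence Sharing in Phage-Bacteria Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binary phage-bacteria killing matrices and the
    genomic relationships of the phages behind them. Implements bipartite Barber
    modularity with leading-eigenvector bisection and Kernighan-Lin tuning, the
    a-posteriori interaction ratio, NODF nestedness, and equiprobable null-model
    significance testing; a host-range concordance statistic based on the
    normalized generalized Jensen-Shannon divergence of killing profiles, with
    species- and genus-level group analyses and the accompanying comparison
    statistics; exact canonical k-mer sharing networks with Mash-style distances
    and mutual information against host sharing; a simplified paired-end read
    simulator and 31-mer pseudo-mapper to quantify cross-recruitment false
    positives; and seeded generators of synthetic interaction matrices,
    taxonomies and genomes with planted structure so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    withr,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
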