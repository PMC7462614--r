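Package: poolpopgen
Title: Pooled Population Genomics: Diversity, Differentiation, Selection
    and the Distribution of Fitness Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic inference from pooled
    whole-genome sequencing of wild populations. Implements pool-seq
    estimators of nucleotide diversity (pi) and Watterson's theta in
    genomic windows with coverage filters, effective population size from
    the population mutation rate, pairwise F_ST at window, gene and SNP
    resolution with a Z-transformed outlier scan and Fisher's exact tests,
    polarization of coding sites against an outgroup pseudogenome into
    zero-fold and four-fold derived allele frequencies, McDonald-Kreitman
    tables with asymptotic alpha, the direction-of-selection (DoS) index,
    site-frequency-spectrum projection, and a gamma likelihood for the
    distribution of fitness effects. A forward Wright-Fisher simulator
    with selection, dominance and recombination generates synthetic study
    systems with known ground truth, including reference and outgroup
    genomes, CDS annotation and pooled read counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    rtracklayer,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
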