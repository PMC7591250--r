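Package: phzscan
Title: Marker-Normalized Quantification of Phenazine Producers and
    Degraders in Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the fraction of phenazine-producing (phz+) and
    phenazine-degrading bacteria in shotgun metagenomes from translated
    best-hit protein searches against a reference catalog of core
    biosynthesis genes (phzA/B, phzD, phzE, phzF, phzG), degradation
    genes (phdA, podA) and 25 universal single-copy marker genes.
    Per-family read counts are normalized to reads per kilobase (RPK);
    the median marker RPK serves as a total-bacteria baseline and trait
    medians are reported as fractions of it. Includes a six-frame
    translated search with banded Smith-Waterman extension, a parser for
    BLAST/DIAMOND tabular output, a synthetic spike-in community
    simulator with exact ground truth, a factorial benchmark computing
    accuracy and detection-limit metrics, and habitat-level survey
    aggregation with rank-sum comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
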