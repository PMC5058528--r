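Package: hostscan
Title: Host-Race Divergence Analysis from Dominant Markers and Nuclear Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting host plant-associated genetic
    divergence in phytophagous insects sampled from two hosts at multiple
    locations. Implements quality control and genotyping-error estimation for
    dominant (AFLP-type) presence/absence markers, allele-frequency and
    F-statistics estimation for dominant data with permutation tests, two-locus
    gametic disequilibrium by EM from dominant phenotypes, an FDist-style
    FST outlier scan against a simulated neutral envelope seeded by a trimmed
    mean FST, EM haplotype phasing of diploid IUPAC-coded sequence data with
    diversity statistics and AMOVA-based PhiST, median-joining haplotype
    networks with outgroup rooting, and Jaccard-distance ordination with
    permutational MANOVA. A seedable synthetic-data generator with recorded
    ground truth supports estimator-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    vegan,
    permute,
    ape,
    igraph,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
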