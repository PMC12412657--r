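Package: fissionkit
Title: Dating and Characterising Chromosomal Fissions from Comparative
    Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing a centric chromosomal fission between two
    closely related genomes with a third genome as outgroup. Implements
    outgroup polarisation of single-nucleotide differences, detection of
    GC-biased clustered substitutions (BCS) and the per-window UBCS excess
    statistic used to date a fission from the onset of neo-telomeric
    GC-biased gene conversion, net-divergence (Da) based dating of derived
    alleles, windowed nucleotide diversity, Dxy and Weir-Cockerham FST with
    region-class rank-sum contrasts, interstitial and terminal telomeric
    repeat scanning, synteny-block based fission/fusion polarisation with
    breakpoint localisation, exonic splicing enhancer disruption scoring and
    exon-skipping consequence prediction, plus seed-deterministic synthetic
    data generators with ground-truth records so every stage is testable
    without large genome assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
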