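Package: wzscan
Title: Sex-Linked Scaffold Discovery and Neo-Sex Chromosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies W- and Z-linked scaffolds in a female bird genome
    assembly from sex-pooled short-read data, using two complementary
    approaches: a Y/W chromosome genome scan (YGS) style single-copy k-mer
    test and a differential read-depth classifier with coverage-fraction
    filters. Builds reference-anchored pseudomolecules, profiles windowed
    read depth to reveal neo-sex chromosomes, segments windowed neo-W/neo-Z
    sequence identity into candidate evolutionary strata, and compares
    gametolog dN/dS (Nei-Gojobori 1986 counting with Jukes-Cantor
    correction) between W and Z gene copies with an exact paired
    signed-rank test. Includes a synthetic-genome generator that emulates
    the statistical structure of female-heterogametic (ZW) resequencing
    studies so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
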