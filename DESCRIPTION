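Package: snpbarcode
Title: Particle Swarm Search for SNP Barcodes Distinguishing Phenotype Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies "SNP barcodes" -- combinations of single-nucleotide
    polymorphisms (SNPs) with fixed genotypes -- whose carrier frequency
    differs maximally between a high-phenotype and a low-phenotype group,
    using a discrete particle swarm optimization (PSO) search with a
    linearly decreasing inertia weight. Includes an exhaustive-search
    oracle for small SNP panels, odds-ratio evaluation of barcodes with
    Woolf confidence intervals, Pearson chi-square tests and noncentral
    chi-square post-hoc power, and a synthetic genotype/phenotype data
    generator with a planted epistatic barcode for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
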