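Package: pofoqtl
Title: Parent-of-Origin Specific Cis-eQTL Mapping in Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of parent-of-origin specific cis expression quantitative
    trait loci (imprinted eQTLs) from mother/father/child trio genotypes and
    offspring expression data. Parental origin of each allele in the child is
    assigned by rules of Mendelian inheritance; cis associations are then run
    separately on the maternally and paternally inherited alleles, on
    reciprocal heterozygote classes, and on conventional diploid dosages, and
    compared with a nested-linear-model likelihood ratio test of imprinting.
    Includes the quality-control and population-stratification filters of the
    screening design, imprinted-gene enrichment testing, a deterministic trio
    cohort simulator with known ground truth, and a pipeline driver with a
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
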