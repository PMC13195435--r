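Package: skypurge
Title: Diversity, Inbreeding, Genetic Load and Genomic-Offset Scans for
    Fragmented Sky-Island Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Population-genomic analysis pipeline for small, fragmented
    (sky-island) plant cohorts genotyped by whole-genome resequencing.
    Implements VCF site filtering and LD pruning; sliding-window nucleotide
    diversity, Tajima's D and Weir-Cockerham Fst; private alleles, LD decay
    and Mantel isolation-by-distance/environment tests; run-of-homozygosity
    detection with F_ROH and F_IS; derived-allele genetic-load tallies
    (SYN/TOL/DEL/LoF ratios and pi0/pi4); joint Fst x ln(pi-ratio) selective
    sweep outliers; genotype-environment association by a latent-factor
    ridge scan and redundancy analysis; and gradient-forest genomic-offset
    projection under future climate grids. Ships a seeded synthetic-cohort
    generator with truth tables emulating a 7-population, 3-lineage design
    with an inbreeding gradient, purging of homozygous deleterious
    genotypes, and environment-associated loci.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    geosphere,
    vcfR,
    ape,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
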