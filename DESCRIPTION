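Package: sorgscreen
Title: Locus-Targeted Screening for Deleterious Alleles in Sorghum Maturity and Dwarf Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A candidate-gene screening pipeline for deleterious alleles at the
    sorghum Maturity (Ma1, Ma2, Ma3, Ma5, Ma6) and Dwarf (Dw1, Dw2, Dw3) loci.
    Reads panel VCFs restricted to candidate-locus regions, normalizes and
    biallelifies variants, predicts protein-level consequences from first
    principles with HGVS p. nomenclature, classifies effects using externally
    supplied substitution (SIFT-like) scores, genotypes germplasm panels against
    a curated catalog of characterized allele signatures, and tests
    genotype-phenotype associations (group-means linear models, Shapiro-Wilk
    diagnostics, Kruskal-Wallis fallback). A synthetic-data generator produces
    reference sequences, gene models, variant panels and phenotypes with known
    ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
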