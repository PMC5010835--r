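Package: quadprio
Title: Family-Quad Exome Variant Prioritization Under Mendelian Inheritance Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from whole-exome
    sequencing of a nuclear family of four (an affected proband, two
    unaffected parents and an unaffected sibling). Implements a filtering
    cascade over a multi-sample VCF: per-sample genotype-quality and depth
    filters, functional-class restriction to protein-changing variants, a
    family-genotype discard rule, classification under four Mendelian
    inheritance models (dominant de novo, autosomal recessive, compound
    heterozygous without phase, and X-linked), a population rarity rule
    with a gene-level relaxation for compound heterozygotes, and a
    muscle-expressed gene restriction. Ships a quad-pedigree genotype
    simulator (Hardy-Weinberg parental genotypes, Mendelian transmission,
    male X hemizygosity, genotyping error and missingness) with a ground
    truth table so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
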