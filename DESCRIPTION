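Package: hapvar
Title: Haplotype-Inheritance QTL Mapping and Multifunctional Variant
    Prioritization in Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps expression, miRNA and chromatin-accessibility quantitative
    trait loci in a three-generation family by regressing each trait on
    parental haplotype-block inheritance, consolidates ATAC-seq summit calls
    into a master summit atlas with read counting and GC-aware normalization,
    filters whole-genome bisulphite CpG calls for intermediate methylation
    consistent with monoallelic activity, tests allelic imbalance of reads at
    heterozygous sites, and integrates all layers in a variant filtering
    cascade that nominates candidate multifunctional regulatory variants with
    a per-variant evidence ledger and per-stage funnel report. A seeded
    synthetic-study generator emulates every input so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
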