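Package: plptrace
Title: Tracing the Origin of Pathogenic Variants Across Species and Ancient
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for asking where the pathogenic and likely
    pathogenic (PLP) variants of a human disease gene come from. One arm reads
    each variant's orthologous column out of a multi-species whole-genome
    alignment (MAF) and classifies every variant-by-species cell into one of
    six alignment states (shared, wildtype, other base, gap, no aligned base,
    gap with unaligned bases), with an equal-length rule for indels; the other
    arm screens ancient-human read sets for the same variant panel through a
    base-quality-filtered pileup. Cross-tabulations, clade-level Kruskal-Wallis
    comparisons and domain-distribution chi-squared tests summarise both arms.
    Synthetic-data generators (phylogeny-simulated alignments with planted
    shared alleles, ancient read sets with planted carriers and
    deamination-style damage) provide fully-known truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
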