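Package: somaclone
Title: Genome Alteration Analysis for Long-Term Plant Cell Cultures
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and summarises the genome alterations that accumulate in
    long-term asexually propagated plant cell cultures: read-depth based
    copy-number and ploidy classification of genes against an estimated
    hemizygous depth unit, zero-coverage deletion detection, allele-depth
    based zygosity classification with a flanking-coverage exclusion filter,
    variant density and substitution-spectrum summaries, a simplified
    high-impact variant effect annotator, InDel codon-frame enrichment
    analysis, and copy-proportional allele-specific expression contrasts
    with a self-contained Mann-Whitney U test. A truth-labelled synthetic
    aneuploid genome generator emits standard FASTA/GFF3/bedGraph/VCF/TSV
    files so every stage is testable without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    methods,
    jsonlite,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
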