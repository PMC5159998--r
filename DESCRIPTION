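Package: msdinminer
Title: Mining and Mass-Spectrometric Validation of MSDIN Cyclic Peptide
    Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discovery and validation of MSDIN-family cyclic peptide
    precursor genes in Amanita genomes. Provides grammar-based
    partitioning and POPB-processability validation of 33-37 amino acid
    precursor peptides (10-aa leader, 6-10-aa core, 17-aa follower), a
    deterministic six-frame miner for the characteristic two-exon gene
    structure (single 52-58 bp GT/GC..AG intron interrupting the fourth
    codon from the end), monoisotopic mass prediction for head-to-tail
    macrocycles with hydroxylation and tryptathionine combinatorics,
    ppm-space MS1 peak matching, cyclic b-ion fragment ladders for MS/MS
    annotation, core-region amino acid composition statistics, and seeded
    synthetic genome and peak-list generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
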