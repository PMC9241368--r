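Package: tipscan
Title: Discovery, Genotyping and Population Analysis of Transposable
    Element Insertion Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for working with transposable element insertion
    polymorphisms (TIPs) in plant pan-genomes. Classifies structural-variant
    sequences as TE copies under the 80-80 rule, collates per-reference
    insertion calls into a nonredundant locus set, genotypes every locus in
    every accession from short paired-end reads by junction-spanning and
    read-pair mapping patterns (CC/GG/CG/NN codes), and analyses the
    resulting genotype matrix: MAF filtering, allele-sharing distances and
    neighbor-joining trees, variance-standardized PCA, and a Fisher's-exact
    selection scan with -log10/z-score normalization. A synthetic pan-genome
    and read simulator with known truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicAlignments,
    IRanges,
    jsonlite,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
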