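Package: dropinDesign
Title: Design of Drop-In CRISPR Knock-In Donors, Guides and Validation PCR
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for scarless CRISPR-Cas9 knock-in design into coding
    introns. From a reference genome (FASTA), gene annotation (GFF3) and an
    optional strain-variant VCF, the package builds gene models with
    intron-phase information, enumerates and ranks SpCas9 (NGG) guides with
    variant-aware filtering, extracts 100-nt homology arms around the blunt
    cut site, and assembles three donor classes: long-primer PCR/ssDNA
    drop-in donors (lambda-exonuclease strand selection), synthesized
    dsDNA drop-in donors flanked by genome-absent gRNA1 target sites, and
    plasmid donors produced by simulated directional restriction subcloning.
    It simulates the resulting molecules (PCR duplex, surviving ssDNA
    strand, Cas9 linearization fragments, the HDR-edited allele and the
    gene-trap or protein-trap transcript) and designs in/out genotyping PCR
    with 200-800 nt amplicons. A deterministic synthetic-locus generator
    provides reproducible fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
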