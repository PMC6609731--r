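Package: mitoirg4
Title: Inverted Repeats, G-Quadruplex Motifs and Compartment Statistics for
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for organelle genomes carrying large inverted
    repeats. Scans nucleotide sequences for putative G-quadruplex (G4DNA)
    motifs with a run-based window score, detects large inverted repeats from
    finished assemblies (k-mer seeding against the reverse complement with
    X-drop extension) or from read-depth tracks (2-fold coverage), partitions
    genomes into repeat and single-copy regions and into exon/intron/intergenic
    compartments, tests motif enrichment per compartment with a chi-square
    goodness-of-fit test and across species with a phylogenetic paired t-test
    under Pagel's lambda, and computes windowed and cumulative GC-skew
    profiles. Includes a synthetic-genome generator with full ground truth
    (planted repeats, motifs, annotations, depth tracks and tree-structured
    paired traits) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
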