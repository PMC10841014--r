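Package: pareMir
Title: miRNA Quantification and Degradome-Supported Target Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-RNA quantification and degradome (PARE)-based target
    identification for plant miRNAs, modelled on organ-resolved studies in
    the liverwort Marchantia polymorpha. Implements adapter trimming,
    18-28 nt read selection, read collapsing and RPM normalisation of
    small-RNA libraries; gapless antiparallel miRNA:mRNA duplex alignment
    with G:U wobble penalties; per-transcript degradome 5'-end profiles,
    cutting power, cleavage-site categories and a composite 0-18 degradome
    score with T-plot output; 2^-ddCt relative quantification with
    replicate t-tests; a base-pair-maximisation hairpin check for miRNA
    precursors; and a seeded synthetic-data generator producing complete
    ground-truthed datasets (transcriptome, miRNAs, sRNA FASTQ, degradome
    tags, Ct tables) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
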