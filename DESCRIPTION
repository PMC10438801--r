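Package: phagecurate
Title: Curation of Linear Phage Genome Assemblies with Direct Terminal Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves the termini of linear double-stranded DNA phage genome
    assemblies from read-coverage signal and terminal self-repeat search,
    repairs contigs that were collapsed or opened mid-genome, detects and
    trims terminal adapter/barcode flank artifacts and spurious tandem
    duplications unsupported by junction-spanning reads, flags residual
    homopolymer indel errors by pileup discordance, and reorients genomes to
    a canonical start. Ships a simulator of T7-like phage genomes with
    direct terminal repeats, defect injection, and long/short read sampling
    with truth-coordinate SAM alignments so every detector is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
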