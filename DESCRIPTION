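Package: scbulksim
Title: Joint Simulation of Correlated Single-Cell and Bulk DNA Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates paired-end DNA sequencing reads for experiments that
    mix single-cell and bulk samples drawn from a hierarchically grouped
    design (population, biological unit, sample). Mutated diploid prototype
    genomes are forged from a haploid reference; a truncated hierarchical
    Dirichlet mixture induces correlation between samples from the same
    biological unit; single-cell samples pass through a whole-genome
    amplification error model (allelic dropout and false-positive mutations)
    while bulk samples are composed by sampling reads without replacement
    from pure per-prototype read pools. Truth VCF/TSV files are emitted
    alongside the FASTQ output, and a scoring module compares variant-caller
    call sets against the truth (recall, precision, F1, Ti/Tv) with standard
    post-filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
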