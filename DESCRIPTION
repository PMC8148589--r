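Package: seqfu
Title: Robust Manipulation of FASTA and FASTQ Sequence Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coherent suite of FASTA/FASTQ manipulation utilities:
    readers and writers for plain and gzip-compressed files (including the
    multi-line 'Sanger FASTQ' dialect), paired-end read management
    (interleaving, deinterleaving, Illumina lane merging with integrity
    checks), IUPAC-aware oligonucleotide matching on both strands with
    partial end matches, dataset length statistics (N50, auN) with
    MultiQC-ready output, quality-encoding inference and per-position
    quality profiles, sequence dereplication with size-tag propagation and
    a JSON provenance report, six-frame open-reading-frame extraction with
    optional pair joining, and Smith-Waterman local alignment. A
    multi-subcommand command-line interface and a deterministic synthetic
    FASTQ generator for testing are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
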