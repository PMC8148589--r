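---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfu)
```

This vignette documents the models, conventions and numerical choices
behind each component of the package, in the spirit of a methods section:
what each operation computes, which parameters matter, and where a design
was genuinely open and a choice had to be made.

## Record model and parsing

Every operation works on a `seq_tbl`: a data frame with one row per
sequence and columns `name` (first whitespace-delimited header token),
`comment`, `sequence` and `quality` (`NA` for FASTA). Representing a
dataset as a vectorised table rather than a lazy stream is the idiomatic R
trade-off: operations are whole-vector and fast, at the cost of holding
the dataset in memory. The parser itself is record-wise, so malformed
input is reported with the offending record's name, and the memory cost is
proportional to the file, not to any intermediate expansion. For the
dataset sizes the test-suite exercises (up to a few thousand reads) this
is far below any practical limit; users with files that do not fit in
memory should shard them first.

Parsing decisions:

* Format is detected from the first non-blank character (`>` FASTA, `@`
  FASTQ); gzip is detected from the magic bytes `1f 8b`, never from the
  file name, so renamed or piped files behave correctly.
* Multi-line ("Sanger") FASTQ is parsed with an explicit state machine:
  sequence lines are consumed until the `+` separator, then quality lines
  until the quality is exactly as long as the sequence. This is the only
  correct termination rule — a quality line may begin with `@`, so
  lookahead on the first character would misparse valid files. A 4-line
  fast path handles the modern canonical layout.
* A quality shorter than its sequence at end of file is a truncation error
  naming the record; an empty file is an empty table with a warning (empty
  shards are routine in pipelines and should not kill them).
* Output is deliberately bit-stable: FASTA unwrapped unless a line width
  is requested, FASTQ always 4-line, LF endings, header rejoined with a
  single space. CRLF is accepted on input.
* Mate-path inference tries `_R1` → `_R2`, `_1.` → `_2.`, `.1.` → `.2.` in
  that order, and refuses ambiguous names (two candidate tags) rather than
  guessing. These three conventions cover bcl2fastq, SRA and ENA naming;
  the set is a documented superset of what any one instrument writes.

## IUPAC matching

Each IUPAC code is a 4-bit set over {A,C,G,T}; two codes are *compatible*
when their sets intersect (bitwise AND of the masks). This semantics is
symmetric: the query may be a degenerate primer and the target may contain
`N`s, and both are handled by the same rule. The alternative — ambiguity
honoured on the pattern side only — is the stricter primer-matching
convention; the symmetric rule is strictly more permissive and is what a
viewer highlighting matches in real (N-containing) reads needs. This is
stated prominently in the documentation because it means an `N` in a read
matches any query base.

`find_oligo` scans every offset of the query along the forward strand,
including offsets where the query overhangs either target end. Partial
matches are *only* these end-overhangs (the adapter / primer read-through
case); internal sub-matches shorter than the query are not enumerated,
which keeps the hit list linear in target length. Reverse-strand hits are
found by scanning the reverse-complemented query and are reported with
coordinates on the forward strand, which makes the strand-symmetry
property (`-` hit of q at p ⟺ `+` hit of rc(q) at p) hold by
construction and testable.

Defaults: `max_mismatches = 0`, `min_match_length = ceiling(|query|/2)`.
The half-length floor is a pragmatic default for primer work — it always
admits the full match and rejects trivially short overhangs; no published
value exists for these thresholds, so they are package choices. Matching
is case-insensitive; masking (`mask_primers`) writes uppercase `N` over
the union of all hit intervals and never touches the quality string, so
downstream tools still see consistent lengths.

## Length statistics

N50 uses the dominant convention: sort lengths in decreasing order,
accumulate, and report the length at which the running sum first reaches
half the total — always one of the observed lengths, never interpolated.
auN is `sum(L_i^2) / sum(L_i)`, the area under the Nx curve: a
length-weighted mean length that moves smoothly when an assembly changes,
where N50 jumps. `nx_length()` exposes the general Nx. Quality-encoding
inference uses two cutoffs on the minimum observed ASCII code: below 59
can only be Phred+33 (Q ≤ 41 keeps Phred+33 at or below ASCII 74, and
Phred+64 can never dip below 64); at or above 64 it is reported as
Phred+64; the window 59–63 stays `undetermined` (it would require
negative-score Solexa qualities to disambiguate, which the package does
not model). The default inspection limit of 1000 records bounds work on
huge files while being far more than the one record the rule formally
needs.

## Paired-end operations

`interleave` enforces two integrity checks that shell one-liners lack:
equal stream lengths (reporting which side ended first) and per-pair name
agreement after stripping a trailing `/1`/`/2` token — the CASAVA ≥ 1.8
convention, where the mate lives in the comment, passes because both
mates then share the bare name. The check defaults to on for interleaving
but is not applied when merging lanes, where names legitimately differ
across files. Lane grouping parses the bcl2fastq pattern
`<sample>_S<k>_L<lane>_R<mate>_001.fastq[.gz]`; merging re-parses every
record rather than concatenating compressed blocks — slower, but it is
exactly this re-parse that catches a truncated lane, and a failed merge
deletes its partial output so no corrupted dataset survives the error.

## Dereplication

The key is the exact sequence string, case-folded by default;
reverse-complement collapsing is deliberately not performed (it is a
different feature with different downstream semantics). Abundances are
carried in the USEARCH/VSEARCH-compatible `;size=N` header tag: input
tags count as their declared multiplicity, output totals are written back
as tags, so any number of dereplication rounds preserves the original
read counts — the conservation law `sum(sizes) = number of original
reads` is tested as an invariant, along with idempotence and the
equivalence of two-step and one-step dereplication. Spaced `size = N`
variants are accepted on input; the compact form is always written, for
interoperability. Output is ordered by decreasing abundance (what
clustering tools downstream expect), ties by first appearance, and the
JSON report records per-file counts so the origin of every duplicated
sequence remains identifiable. Memory is proportional to the number of
unique sequences.

## ORF extraction and pair joining

Translation uses the standard genetic code. Degenerate codons are
resolved by expansion: if all concrete readings agree the codon
translates normally (`GCN` → `A`); if they disagree but none is a stop it
is `X`; if stops and non-stops are both possible the codon is treated as
undeterminable and *breaks* ORF runs — the conservative reading, under
which an all-`N` sequence contains no ORFs rather than one giant `X` run.
An ORF is a maximal codon run between stops in one of the six frames,
optionally required to begin at the run's first `ATG` and/or to end at a
real stop. The stop codon is excluded from both the peptide and the
reported span, so `nt_length = 3 × |peptide|` holds exactly. Coordinates
are always 0-based half-open on the forward strand, also for negative
frames. The default `min_aa = 25` is a conventional short-protein floor;
the filter is exposed because no single value suits all uses.

Pair joining is a deliberately simple best-overlap merge, not a
probabilistic merger: reverse-complement the reverse mate, try every
overlap length from the maximum down to `min_overlap` (default 10),
keep the one with the fewest mismatches (ties prefer the longest
overlap), and accept it if its mismatch fraction is at most 0.1. In the
accepted overlap each base is taken from the mate with the higher quality
at that position. If no overlap qualifies the mates are joined with a
10-`N` spacer so both are still scanned for ORFs — a fragment is never
silently dropped. The synthetic paired fixtures are built from a shared
fragment (forward read = prefix, reverse read = reverse-complemented
suffix), so the merge is tested by exact fragment reconstruction.

## Local alignment

`smith_waterman` implements the textbook local-alignment dynamic
programme with a linear gap penalty (defaults 3 / −3 / −2); affine gaps
are a possible extension but would change the recurrence, and the linear
model is what the classic formulation defines. Determinism choices:
traceback prefers diagonal, then up, then left; among equal maximal cells
the smallest `(i, j)` wins. `N` scores as a mismatch against everything,
including another `N`, so uncertain bases cannot anchor alignments.
Scores are cross-checked in the test-suite against an independent
implementation (`Biostrings::pairwiseAlignment` with gap opening 0) over
a grid of schemes, and every traceback is verified by re-scoring the two
gapped strings.

## Synthetic data generator

`sim_records()` / `generate_fastq()` generate all test inputs; given a
seed the output is byte-identical (the generator saves and restores the
caller's RNG state). What it emulates, and what it does not:

* Templates are uniform random DNA. Real genomic sequence has composition
  bias, repeats and homopolymers; none of that matters for the exact
  string operations tested here, but it means the package's tests say
  nothing about, e.g., aligner heuristics on repetitive DNA.
* The default quality profile declines from about Q36 at the read start
  to about Q15 at the end (Gaussian noise, sd 4, clamped to the
  encoding's legal range) — the familiar Illumina within-read decline.
  There is no instrument error *model*: bases are not actually mutated
  according to quality, so quality-aware consumers are tested on
  structure, not on error statistics.
* Paired reads derive from a shared fragment of 1.6 × read length by
  default, giving a true overlap of 0.4 × read length for merge tests.
* The duplication map plants exact copy counts for dereplication tests;
  planted oligos are spliced in verbatim (reverse-complemented for `-`)
  at fixed positions for matcher tests.

## Problem sizes and determinism in the test-suite

The suite checks each operation against an independently written oracle
(IUPAC expansion + fixed-string search, sort/cumulate/scan, six-frame
enumeration via the Biostrings genetic code, `pairwiseAlignment` scores)
on randomised inputs under fixed seeds: 1000 read pairs for the
interleave round trip, 100 length multisets (up to 1000 lengths of up to
1e5), 100 random pairs × 3 scoring schemes for alignment, 200 sequences
of up to 300 nt × 3 length filters for ORFs, and full-coverage query
lengths 1–8 for the matcher. These sizes make the whole suite run in well
under a minute while every property is exercised across hundreds of
random instances; all seeds are fixed in the tests, so failures
reproduce.

## Command-line interface

The R functions are the primary interface; `seqfu_main()` exposes them as
the familiar multi-subcommand shell tool, with thin launchers installed
under `inst/bin` (`seqfu`, `fu-orf`, `fu-sw`, `fu-primers`). Conventions:
data to standard output unless `-o` is given, diagnostics to standard
error, exit 0 on success, 1 on usage errors, 2 on data/integrity errors
(a mismatched pair, a truncated file). ANSI colour in `seqfu view` is
emitted only on a terminal, so piped output stays plain.
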