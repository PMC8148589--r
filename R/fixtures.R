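# Deterministic synthetic FASTQ/FASTA generator.  Every test in the suite
# draws its inputs from here: given the same specification and seed the
# output is byte-identical.  The generator emulates the structural features
# the tools operate on — read pairing derived from a shared fragment (so
# overlap joining can reconstruct it), exact planted duplicate counts,
# planted oligonucleotides, and Phred qualities drawn around a positional
# mean profile — not the error model of a real sequencer.

# run code with a private RNG state so generation is reproducible without
# disturbing the caller's random stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# qualities: one string per read, around the per-position mean profile,
# clamped to the encoding's legal range.  The default profile mimics the
# within-read quality decline of Illumina data: high near the start,
# tailing off towards the 3' end, so every read spans a wide Phred range.
random_quals <- function(n, len, offset, profile = NULL, sd = 4) {
  if (is.null(profile)) profile <- seq(36, 15, length.out = len)
  profile <- rep_len(profile, len)
  qmax <- if (offset == 33L) 41L else 40L
  vapply(seq_len(n), function(i) {
    q <- round(stats::rnorm(len, mean = profile, sd = sd))
    q <- pmin(pmax(q, 0L), qmax)
    intToUtf8(q + offset)
  }, character(1))
}

plant_oligo <- function(seqs, oligo, position, strand) {
  ins <- if (strand == "-") suppressWarnings(reverse_complement(oligo))
         else oligo
  vapply(seqs, function(s) {
    stopifnot(position + nchar(ins) <= nchar(s))
    paste0(substr(s, 1, position), ins,
           substr(s, position + nchar(ins) + 1, nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate deterministic synthetic reads in memory
#'
#' The building block behind [generate_fastq()].  Templates are uniform
#' random DNA; `duplication` turns template ranks into exact copy counts
#' (templates without an entry appear once), `planted_oligos` overwrites a
#' fixed window of every read with a given oligonucleotide (reverse
#' complemented for strand `-`), and paired mode derives both mates from a
#' longer fragment: R1 is its prefix, R2 the reverse complement of its
#' suffix, so a correct overlap merge reconstructs the fragment.
#'
#' @param n_records number of templates (before duplication).
#' @param read_length single length or `c(min, max)` range.
#' @param paired generate R1/R2 mates from shared fragments.
#' @param fragment_length fragment size in paired mode (default
#'   `round(1.6 * read_length)`, i.e. mates overlap by about 40% of a read).
#' @param phred_offset 33 or 64.
#' @param quality_profile per-position mean Phred scores (recycled).
#' @param duplication named integer vector: copy count per template rank
#'   (`"1"` = first template).
#' @param planted_oligos list of `list(oligo=, position=, strand=)` entries;
#'   `position` is 0-based.
#' @param seed integer seed; same seed, same records.
#' @param basename prefix for read names.
#' @return a [seq_records()] table, or for `paired` a list with elements
#'   `r1`, `r2` and `fragments` (the template fragments each pair came
#'   from).
#' @export
sim_records <- function(n_records, read_length = 100L, paired = FALSE,
                        fragment_length = NULL, phred_offset = 33L,
                        quality_profile = NULL, duplication = NULL,
                        planted_oligos = NULL, seed = 42L,
                        basename = "read") {
  stopifnot(n_records >= 0L, phred_offset %in% c(33L, 64L))
  with_seed(seed, {
    if (n_records == 0L) {
      return(if (paired) list(r1 = empty_seq_tbl(), r2 = empty_seq_tbl(),
                              fragments = empty_seq_tbl())
             else empty_seq_tbl())
    }
    lens <- if (length(read_length) == 2L) {
      sample(read_length[1]:read_length[2], n_records, replace = TRUE)
    } else rep.int(as.integer(read_length), n_records)

    if (paired) {
      rl <- max(lens)
      lens <- rep.int(rl, n_records)
      fl <- if (is.null(fragment_length)) as.integer(round(1.6 * rl))
            else as.integer(fragment_length)
      stopifnot(fl >= rl)
      frags <- random_dna(n_records, fl)
      nm <- sprintf("%s_%d", basename, seq_len(n_records))
      s1 <- substr(frags, 1L, rl)
      s2 <- suppressWarnings(
        reverse_complement(substr(frags, fl - rl + 1L, fl)))
      if (!is.null(planted_oligos)) {
        for (po in planted_oligos) {
          s1 <- plant_oligo(s1, po$oligo, po$position, po$strand)
        }
      }
      q1 <- random_quals(n_records, rl, phred_offset, quality_profile)
      q2 <- random_quals(n_records, rl, phred_offset, quality_profile)
      return(list(
        r1 = seq_records(nm, s1, comment = "1:N:0:1", quality = q1),
        r2 = seq_records(nm, s2, comment = "2:N:0:1", quality = q2),
        fragments = seq_records(nm, frags)
      ))
    }

    seqs <- mapply(function(i, l) random_dna(1L, l), seq_len(n_records),
                   lens)
    if (!is.null(planted_oligos)) {
      for (po in planted_oligos) {
        seqs <- plant_oligo(seqs, po$oligo, po$position, po$strand)
      }
    }
    # expand duplication map: rank -> exact copy count
    copies <- rep.int(1L, n_records)
    if (!is.null(duplication)) {
      ranks <- as.integer(names(duplication))
      stopifnot(all(ranks >= 1L), all(ranks <= n_records))
      copies[ranks] <- as.integer(duplication)
    }
    idx <- rep.int(seq_len(n_records), copies)
    nm <- sprintf("%s_%d", basename, seq_along(idx))
    quals <- vapply(seq_along(idx), function(k) {
      random_quals(1L, lens[idx[k]], phred_offset, quality_profile)
    }, character(1))
    seq_records(nm, seqs[idx], quality = quals)
  })
}

#' Write deterministic synthetic FASTQ files
#'
#' File-level wrapper around [sim_records()]: paired mode writes
#' `<basename>_R1.fastq.gz` and `<basename>_R2.fastq.gz` with
#' mate-consistent names, unpaired mode writes `<basename>.fastq.gz`
#' (plain `.fastq` with `gzip = FALSE`).
#'
#' @inheritParams sim_records
#' @param out_dir output directory (created if missing).
#' @param gzip compress the output files (default `TRUE`).
#' @return character vector of the file paths written.
#' @export
generate_fastq <- function(out_dir, n_records, read_length = 100L,
                           paired = FALSE, fragment_length = NULL,
                           phred_offset = 33L, quality_profile = NULL,
                           duplication = NULL, planted_oligos = NULL,
                           seed = 42L, basename = "sample", gzip = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  recs <- sim_records(n_records, read_length = read_length, paired = paired,
                      fragment_length = fragment_length,
                      phred_offset = phred_offset,
                      quality_profile = quality_profile,
                      duplication = duplication,
                      planted_oligos = planted_oligos, seed = seed,
                      basename = basename)
  if (paired) {
    p1 <- file.path(out_dir, paste0(basename, "_R1", ext))
    p2 <- file.path(out_dir, paste0(basename, "_R2", ext))
    write_seqs(recs$r1, p1, format = "fastq")
    write_seqs(recs$r2, p2, format = "fastq")
    c(p1, p2)
  } else {
    p <- file.path(out_dir, paste0(basename, ext))
    write_seqs(recs, p, format = "fastq")
    p
  }
}
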