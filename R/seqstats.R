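# Dataset-level statistics: length statistics (N50, auN), paired-aware
# counting, quality-encoding inference, positional quality profile, and the
# raw / pretty / MultiQC output dialects.

#' Length statistics of a sequence set
#'
#' N50 follows the dominant convention: the length of the sequence at which
#' the cumulative sum of lengths sorted in decreasing order first reaches at
#' least half the total.  auN is the area under the Nx curve,
#' `sum(L_i^2) / sum(L_i)` — a length-weighted mean length that, unlike N50,
#' varies smoothly with the data.
#'
#' @param lengths vector of positive integer sequence lengths, or a
#'   [seq_records()] table (its sequence lengths are used).
#' @return a list of class `length_stats`: `count`, `total_bp`, `min_len`,
#'   `max_len`, `mean_len`, `n50`, `aun`.
#' @examples
#' length_stats(c(5, 4, 3, 2, 1))  # N50 = 4, auN = 55/15
#' @export
length_stats <- function(lengths) {
  if (inherits(lengths, "data.frame")) lengths <- nchar(lengths$sequence)
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("no sequences: cannot compute statistics",
                                  call. = FALSE)
  if (any(lengths < 1)) stop("sequence lengths must be positive", call. = FALSE)
  total <- sum(lengths)
  structure(list(
    count = length(lengths),
    total_bp = total,
    min_len = min(lengths),
    max_len = max(lengths),
    mean_len = total / length(lengths),
    n50 = nx_length(lengths, 50),
    aun = sum(lengths^2) / total
  ), class = "length_stats")
}

#' Nx length statistic
#'
#' The length L such that sequences of length >= L cover at least x percent
#' of the total bases.  `nx_length(lengths, 50)` is the N50.  Nx is
#' non-increasing in x.
#'
#' @param lengths vector of positive lengths.
#' @param x percentage in (0, 100].
#' @return one of the observed lengths.
#' @export
nx_length <- function(lengths, x = 50) {
  stopifnot(x > 0, x <= 100)
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(sorted)
  sorted[which(cum >= sum(sorted) * x / 100)[1]]
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf(
    "%d sequences, %s bp (min %s, avg %.1f, max %s)\nN50 = %s, auN = %.2f\n",
    x$count, format(x$total_bp, big.mark = ","),
    format(x$min_len), x$mean_len, format(x$max_len),
    format(x$n50), x$aun))
  invisible(x)
}

#' Count reads, folding paired files together
#'
#' Detects R1/R2 pairs among the supplied paths (via [infer_mate_path()])
#' and reports each paired dataset once, with the R1 count.  When the two
#' mates disagree in read count the pair is flagged `PAIR_MISMATCH` — the
#' integrity check that makes silent pair corruption visible.
#'
#' @param paths character vector of FASTA/FASTQ file paths.
#' @return a data frame with columns `path`, `mate_path` (`NA` for unpaired
#'   files), `count` and `status` (`"OK"` or `"PAIR_MISMATCH"`).
#' @export
count_paired <- function(paths) {
  counts <- vapply(paths, function(p) nrow(read_seqs(p)), integer(1))
  mates <- vapply(paths, function(p) {
    m <- tryCatch(infer_mate_path(p), error = function(e) NA_character_)
    if (!is.na(m) && m %in% paths && m != p) m else NA_character_
  }, character(1))
  is_r2 <- paths %in% mates[!is.na(mates)]
  keep <- which(!is_r2)
  res <- data.frame(
    path = paths[keep],
    mate_path = unname(mates[keep]),
    count = unname(counts[keep]),
    status = "OK",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(res))) {
    if (!is.na(res$mate_path[i]) &&
        counts[[res$mate_path[i]]] != res$count[i]) {
      res$status[i] <- "PAIR_MISMATCH"
    }
  }
  rownames(res) <- NULL
  res
}

#' Infer the Phred quality encoding of FASTQ records
#'
#' Inspects the quality strings of up to `sample_limit` records.  A minimum
#' observed ASCII code below 59 can only arise under Phred+33 ("Illumina
#' 1.8+"); a minimum of 64 or above indicates the legacy Phred+64 encoding
#' ("Illumina 1.3-1.7").  Codes confined to the 59-63 window are ambiguous
#' and reported as undetermined.  (Solexa+64, with its negative scores, is
#' not distinguished.)
#'
#' @param records a [seq_records()] table with quality strings.
#' @param sample_limit maximum number of records to inspect (default 1000).
#' @return a list: `encoding_label`, `offset` (33, 64, or `NA`), `min_char`,
#'   `max_char` (ASCII codes), `records_sampled`.
#' @export
infer_quality_encoding <- function(records, sample_limit = 1000L) {
  stopifnot(sample_limit >= 1L)
  if (nrow(records) == 0L || anyNA(records$quality)) {
    stop("quality encoding inference needs FASTQ records with qualities",
         call. = FALSE)
  }
  sample <- utils::head(records$quality, sample_limit)
  codes <- utf8ToInt(paste(sample, collapse = ""))
  lo <- min(codes); hi <- max(codes)
  if (lo < 59L) {
    label <- "Illumina 1.8+ (Phred+33)"; offset <- 33L
  } else if (lo >= 64L) {
    label <- "Illumina 1.3-1.7 (Phred+64)"; offset <- 64L
  } else {
    label <- "undetermined"; offset <- NA_integer_
  }
  list(encoding_label = label, offset = offset,
       min_char = lo, max_char = hi, records_sampled = length(sample))
}

#' Per-position mean quality profile
#'
#' @param records a [seq_records()] table with quality strings.
#' @param offset Phred offset, 33 or 64.
#' @return a list: `per_position_mean_q` (mean Phred score at each read
#'   position, over the reads long enough to cover it) and
#'   `per_position_depth` (how many reads contributed).
#' @export
quality_profile <- function(records, offset = 33L) {
  if (!offset %in% c(33L, 64L)) {
    stop("offset must be 33 or 64", call. = FALSE)
  }
  if (nrow(records) == 0L || anyNA(records$quality)) {
    stop("quality profile needs FASTQ records with qualities", call. = FALSE)
  }
  lens <- nchar(records$quality)
  maxlen <- max(lens)
  sums <- numeric(maxlen)
  depth <- integer(maxlen)
  for (q in records$quality) {
    v <- utf8ToInt(q) - offset
    idx <- seq_along(v)
    sums[idx] <- sums[idx] + v
    depth[idx] <- depth[idx] + 1L
  }
  list(per_position_mean_q = sums / depth, per_position_depth = depth)
}

#' Format length statistics as raw, pretty, or MultiQC text
#'
#' @param stats a named list of [length_stats()] objects (names label the
#'   files), or a single `length_stats` object.
#' @param mode `"raw"` (TSV, one header line), `"pretty"` (aligned table),
#'   or `"multiqc"` (the raw TSV preceded by MultiQC custom-content
#'   front-matter comments, ready for `multiqc` to pick up as a table).
#' @return a character scalar.
#' @export
format_stats <- function(stats, mode = c("raw", "pretty", "multiqc")) {
  mode <- match.arg(mode)
  if (inherits(stats, "length_stats")) stats <- list(sample = stats)
  if (length(stats) == 0L) stop("no statistics to format", call. = FALSE)
  labels <- names(stats)
  if (is.null(labels)) labels <- paste0("file", seq_along(stats))
  tab <- data.frame(
    File = labels,
    `#Seq` = vapply(stats, function(s) s$count, numeric(1)),
    `Total bp` = vapply(stats, function(s) s$total_bp, numeric(1)),
    Avg = sprintf("%.2f", vapply(stats, function(s) s$mean_len, numeric(1))),
    N50 = vapply(stats, function(s) s$n50, numeric(1)),
    auN = sprintf("%.2f", vapply(stats, function(s) s$aun, numeric(1))),
    Min = vapply(stats, function(s) s$min_len, numeric(1)),
    Max = vapply(stats, function(s) s$max_len, numeric(1)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  header <- paste(colnames(tab), collapse = "\t")
  rows <- apply(tab, 1, paste, collapse = "\t")
  raw <- paste(c(header, rows), collapse = "\n")
  switch(mode,
    raw = raw,
    multiqc = paste(c(
      "# id: seqfu_stats",
      "# section_name: Sequence statistics",
      "# plot_type: table",
      raw), collapse = "\n"),
    pretty = {
      cells <- rbind(colnames(tab), as.matrix(format(tab)))
      widths <- apply(nchar(cells), 2, max)
      lines <- apply(cells, 1, function(r) {
        paste(mapply(formatC, r, width = widths), collapse = "  ")
      })
      paste(lines, collapse = "\n")
    })
}
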