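# Paired-end dataset management: interleave, deinterleave, Illumina lane
# grouping and merging.  Each operation enforces the integrity checks that
# ad hoc shell one-liners silently skip: equal stream lengths, consistent
# mate names, parseable input, and no partial output left on failure.

# strip a trailing /1 or /2 mate token from read names
strip_mate_token <- function(names) sub("/[12]$", "", names)

#' Interleave two paired read streams
#'
#' Produces the order `r1[1], r2[1], r1[2], r2[2], ...` so each forward read
#' is immediately followed by its mate.  Unequal stream lengths are an
#' error.  With `check_names` (the default) each pair's names must agree
#' after stripping a trailing `/1`/`/2` token; the CASAVA >= 1.8 style,
#' where the mate is a leading digit of the comment, passes unchanged since
#' both mates then share the bare name.
#'
#' @param r1,r2 [seq_records()] tables of forward and reverse reads.
#' @param check_names verify mate name consistency per pair.
#' @return the interleaved [seq_records()] table.
#' @export
interleave <- function(r1, r2, check_names = TRUE) {
  if (nrow(r1) != nrow(r2)) {
    short <- if (nrow(r1) < nrow(r2)) "forward (R1)" else "reverse (R2)"
    stop("pairing error: the ", short, " stream ended first (",
         nrow(r1), " vs ", nrow(r2), " records)", call. = FALSE)
  }
  if (check_names && nrow(r1) > 0) {
    a <- strip_mate_token(r1$name)
    b <- strip_mate_token(r2$name)
    bad <- which(a != b)
    if (length(bad) > 0) {
      stop("name mismatch at pair ", bad[1], ": '", r1$name[bad[1]],
           "' vs '", r2$name[bad[1]], "'", call. = FALSE)
    }
  }
  if (nrow(r1) == 0L) return(r1)
  idx <- as.vector(rbind(seq_len(nrow(r1)), nrow(r1) + seq_len(nrow(r2))))
  out <- rbind(r1, r2)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("seq_tbl", "data.frame"))
}

#' Split an interleaved stream into separate pairs
#'
#' Odd-positioned records (1st, 3rd, ...) go to the first output, even ones
#' to the second.  An odd total count means a dangling record and is an
#' error.
#'
#' @param records an interleaved [seq_records()] table.
#' @return a list of two [seq_records()] tables, `r1` and `r2`.
#' @export
deinterleave <- function(records) {
  n <- nrow(records)
  if (n %% 2L != 0L) {
    stop("dangling record: interleaved input has an odd number of records (",
         n, ")", call. = FALSE)
  }
  odd <- seq_len(n) %% 2L == 1L
  r1 <- records[odd, , drop = FALSE]
  r2 <- records[!odd, , drop = FALSE]
  rownames(r1) <- NULL; rownames(r2) <- NULL
  list(r1 = structure(r1, class = c("seq_tbl", "data.frame")),
       r2 = structure(r2, class = c("seq_tbl", "data.frame")))
}

# Illumina bcl2fastq naming: <sample>_S<k>_L<lane>_R<mate>_001.fastq[.gz]
LANE_PATTERN <- "^(.*)_S(\\d+)_L(\\d{3})_R([12])_001\\.(fastq|fq)(\\.gz)?$"

#' Group lane-split Illumina files by sample and mate
#'
#' Files following the bcl2fastq convention
#' `<sample>_S<k>_L<lane>_R<mate>_001.fastq[.gz]` are grouped by
#' (sample, mate) and ordered by lane number.  Non-conforming filenames are
#' skipped with a warning (or an error with `strict`).  Single-lane groups
#' are still returned; merging them is then a validated copy.
#'
#' @param paths character vector of file paths.
#' @param strict error instead of warn on non-conforming names.
#' @return a list of lane groups, each a list with `sample_id`, `mate`
#'   (`"R1"`/`"R2"`) and `lane_files` (paths ordered by lane).
#' @export
group_lanes <- function(paths, strict = FALSE) {
  base <- basename(paths)
  ok <- grepl(LANE_PATTERN, base)
  if (any(!ok)) {
    msg <- paste0("not in Illumina lane naming, skipped: ",
                  paste(base[!ok], collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  paths <- paths[ok]; base <- base[ok]
  if (length(paths) == 0L) return(list())
  sample <- sub(LANE_PATTERN, "\\1", base)
  lane <- as.integer(sub(LANE_PATTERN, "\\3", base))
  mate <- paste0("R", sub(LANE_PATTERN, "\\4", base))
  key <- paste(sample, mate, sep = "\r")
  groups <- lapply(unique(key), function(k) {
    i <- which(key == k)
    i <- i[order(lane[i])]
    list(sample_id = sample[i[1]], mate = mate[i[1]], lane_files = paths[i])
  })
  groups
}

#' Merge the lane files of one group into a single FASTQ
#'
#' Concatenates the records of all lanes in lane order into
#' `<sample>_R<mate>.fastq.gz` inside `out_dir`.  Every input file is fully
#' parsed while copying, so a truncated or malformed lane aborts the merge —
#' and a failed merge removes its partial output rather than leaving a
#' corrupted dataset behind.
#'
#' @param group one element of [group_lanes()] output.
#' @param out_dir output directory (must exist).
#' @param overwrite allow replacing an existing output file.
#' @return the output file path, invisibly the record count as attribute
#'   `"count"`.
#' @export
merge_lanes <- function(group, out_dir, overwrite = FALSE) {
  stopifnot(length(group$lane_files) >= 1L)
  out <- file.path(out_dir, paste0(group$sample_id, "_", group$mate,
                                   ".fastq.gz"))
  if (file.exists(out) && !overwrite) {
    stop("output '", out, "' already exists (use overwrite = TRUE)",
         call. = FALSE)
  }
  con <- gzfile(out, "wb")
  n_written <- 0L
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok && file.exists(out)) unlink(out)
  })
  for (f in group$lane_files) {
    recs <- read_seqs(f)  # parse error here aborts and triggers cleanup
    if (nrow(recs) > 0 && anyNA(recs$quality)) {
      stop("lane file '", f, "' is not FASTQ", call. = FALSE)
    }
    if (nrow(recs) > 0) {
      writeLines(paste0("@", seq_headers(recs), "\n", recs$sequence,
                        "\n+\n", recs$quality), con, sep = "\n")
    }
    n_written <- n_written + nrow(recs)
  }
  ok <- TRUE
  structure(out, count = n_written)
}
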