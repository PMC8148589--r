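# IUPAC-aware oligonucleotide matching.
#
# Every IUPAC code denotes a set of nucleotides, encoded here as a 4-bit
# mask (A=1, C=2, G=4, T=8).  Two codes are compatible when their sets
# intersect, i.e. when the bitwise AND of the masks is non-zero.  This
# set-intersection semantics is deliberately symmetric: both the query and
# the target may carry ambiguity codes (reads routinely contain N).

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

IUPAC_ALPHABET <- names(IUPAC_BITS)

# internal: one sequence string -> integer vector of IUPAC bitmasks;
# characters outside the alphabet get NA (strict) or 15 (= N, lenient)
iupac_mask <- function(seq, lenient = TRUE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bits <- unname(IUPAC_BITS[chars])
  if (anyNA(bits)) {
    if (!lenient) {
      bad <- chars[which(is.na(bits))[1]]
      stop("non-IUPAC character '", bad, "' in sequence", call. = FALSE)
    }
    bits[is.na(bits)] <- 15L
  }
  bits
}

#' Reverse complement of (possibly degenerate) DNA
#'
#' Complements every base using the full IUPAC table (A<->T, C<->G, R<->Y,
#' S<->S, W<->W, K<->M, B<->V, D<->H, N<->N) and reverses the result.  Case
#' is preserved.  Characters outside the IUPAC alphabet become `N` with a
#' warning, or an error when `strict = TRUE`.
#'
#' @param seq character vector of DNA strings.
#' @param strict error (instead of warn) on non-IUPAC characters.
#' @return character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("ACGT")   # palindrome
#' reverse_complement("RYN")    # "NRY"
#' @export
reverse_complement <- function(seq, strict = FALSE) {
  from <- paste0(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(tolower(names(IUPAC_COMPLEMENT)), collapse = ""))
  to <- paste0(paste(unname(IUPAC_COMPLEMENT), collapse = ""),
               paste(tolower(unname(IUPAC_COMPLEMENT)), collapse = ""))
  bad <- grepl(sprintf("[^%s]", from), seq)
  if (any(bad)) {
    if (strict) {
      stop("non-IUPAC characters in input sequence", call. = FALSE)
    }
    warning("non-IUPAC characters replaced with 'N'", call. = FALSE)
    seq[bad] <- gsub(sprintf("[^%s]", from), "N", seq[bad])
  }
  comp <- chartr(from, to, seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Are two IUPAC codes compatible?
#'
#' Two codes match when the nucleotide sets they denote intersect, e.g.
#' `R` = \{A,G\} is compatible with `A`, `G`, `S`, `N` but not with `C` or
#' `Y`.  Comparison is case-insensitive.
#'
#' @param pattern_base,target_base single IUPAC characters (vectorised).
#' @param strict error on characters outside the IUPAC alphabet (otherwise
#'   they are treated as `N`).
#' @return logical vector.
#' @examples
#' iupac_compatible("N", "A")  # TRUE
#' iupac_compatible("R", "C")  # FALSE
#' @export
iupac_compatible <- function(pattern_base, target_base, strict = FALSE) {
  p <- unname(IUPAC_BITS[toupper(pattern_base)])
  t <- unname(IUPAC_BITS[toupper(target_base)])
  if (strict && (anyNA(p) || anyNA(t))) {
    stop("non-IUPAC character", call. = FALSE)
  }
  p[is.na(p)] <- 15L
  t[is.na(t)] <- 15L
  bitwAnd(p, t) > 0L
}

# internal: scan one orientation of a query (as bitmask vector) against a
# target mask vector; returns a data.frame of hits on the forward frame of
# `target_mask`.  Partial matches are query overhangs at either target end.
scan_mask <- function(target_mask, query_mask, max_mismatches,
                      min_match_length) {
  tl <- length(target_mask)
  ql <- length(query_mask)
  res_pos <- integer(0); res_len <- integer(0); res_mm <- integer(0)

  # full-overlap offsets, vectorised across all start positions
  if (tl >= ql) {
    n_off <- tl - ql + 1L
    mm <- integer(n_off)
    for (j in seq_len(ql)) {
      mm <- mm + as.integer(
        bitwAnd(target_mask[j:(j + n_off - 1L)], query_mask[j]) == 0L
      )
    }
    keep <- which(mm <= max_mismatches & ql >= min_match_length)
    res_pos <- keep - 1L
    res_len <- rep.int(ql, length(keep))
    res_mm <- mm[keep]
  }

  # left overhang: query start before target start (overlap = query suffix)
  max_over <- min(ql - 1L, tl)
  ov_range <- seq_len(max_over)
  ov_range <- ov_range[ov_range >= min_match_length & ov_range < ql]
  for (ov in ov_range) {
    mm <- sum(bitwAnd(target_mask[seq_len(ov)],
                      query_mask[(ql - ov + 1L):ql]) == 0L)
    if (mm <= max_mismatches) {
      res_pos <- c(res_pos, 0L)
      res_len <- c(res_len, ov)
      res_mm <- c(res_mm, as.integer(mm))
    }
  }
  # right overhang: query end past target end (overlap = query prefix)
  for (ov in ov_range) {
    mm <- sum(bitwAnd(target_mask[(tl - ov + 1L):tl],
                      query_mask[seq_len(ov)]) == 0L)
    if (mm <= max_mismatches) {
      res_pos <- c(res_pos, tl - ov)
      res_len <- c(res_len, ov)
      res_mm <- c(res_mm, as.integer(mm))
    }
  }
  data.frame(position = res_pos, length = res_len, mismatches = res_mm)
}

#' Locate an IUPAC oligonucleotide in a target sequence
#'
#' Scans every alignment offset of `query` against the forward strand of the
#' target, including offsets where the query overhangs either target end
#' (partial matches, the adapter read-through case); internal matches
#' shorter than the query are not reported.  A hit is reported when the
#' overlapping length is at least `min_match_length` and the number of
#' incompatible positions within the overlap is at most `max_mismatches`.
#' With `search_reverse` the reverse-complemented query is also scanned and
#' reported on strand `-`, with the position still on the forward strand.
#' Compatibility is the symmetric IUPAC set-intersection rule of
#' [iupac_compatible()]; both sides may be degenerate.
#'
#' @param target a single sequence string or a one-row [seq_records()] table.
#' @param query IUPAC DNA string (non-empty).
#' @param max_mismatches maximum incompatible positions inside the overlap.
#' @param min_match_length minimum overlap length for a reportable hit;
#'   defaults to half the query length (rounded up), so a full match is
#'   always reportable.  Must not exceed the query length.
#' @param search_reverse also search the reverse strand.
#' @return a data frame with one row per hit: `position` (0-based start on
#'   the forward strand), `strand` (`"+"`/`"-"`), `length` (matched bases),
#'   `mismatches`, and `partial` (`TRUE` when the matched length is shorter
#'   than the query).  Sorted by position, then strand.
#' @examples
#' find_oligo("GGAGTGG", "ARY", min_match_length = 3)
#' @export
find_oligo <- function(target, query, max_mismatches = 0L,
                       min_match_length = ceiling(nchar(query) / 2),
                       search_reverse = TRUE) {
  if (inherits(target, "data.frame")) {
    stopifnot(nrow(target) == 1L)
    target <- target$sequence
  }
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  if (min_match_length < 1L || min_match_length > nchar(query)) {
    stop("min_match_length must be between 1 and the query length",
         call. = FALSE)
  }
  tmask <- iupac_mask(target)
  ql <- nchar(query)

  fwd <- scan_mask(tmask, iupac_mask(query), max_mismatches, min_match_length)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (search_reverse) {
    rev <- scan_mask(tmask, iupac_mask(suppressWarnings(
      reverse_complement(query))), max_mismatches, min_match_length)
    rev$strand <- rep("-", nrow(rev))
    hits <- rbind(hits, rev)
  }
  hits$partial <- hits$length < ql
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("position", "strand", "length", "mismatches", "partial")]
}

#' Mask primer occurrences with N
#'
#' Every base covered by any [find_oligo()] hit of any primer, on either
#' strand, is replaced with `N` (uppercase).  The quality string, name and
#' comment are unchanged, so read length bookkeeping is preserved.
#'
#' @param record a one-row [seq_records()] table.
#' @param primers non-empty character vector of IUPAC primer strings.
#' @param max_mismatches,min_match_length passed to [find_oligo()];
#'   `min_match_length = NULL` (default) uses each primer's own default.
#' @return the record with primer-covered bases masked.
#' @export
mask_primers <- function(record, primers, max_mismatches = 0L,
                         min_match_length = NULL) {
  if (length(primers) == 0L) {
    stop("`primers` must contain at least one primer", call. = FALSE)
  }
  stopifnot(inherits(record, "data.frame"), nrow(record) == 1L)
  len <- nchar(record$sequence)
  covered <- logical(len)
  for (p in primers) {
    mml <- if (is.null(min_match_length)) ceiling(nchar(p) / 2)
           else min_match_length
    hits <- find_oligo(record$sequence, p, max_mismatches = max_mismatches,
                       min_match_length = mml, search_reverse = TRUE)
    for (k in seq_len(nrow(hits))) {
      span <- seq.int(hits$position[k] + 1L,
                      hits$position[k] + hits$length[k])
      covered[span] <- TRUE
    }
  }
  if (any(covered)) {
    chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
    chars[covered] <- "N"
    record$sequence <- paste(chars, collapse = "")
  }
  record
}
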