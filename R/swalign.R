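# Smith-Waterman local alignment with a linear gap penalty.
#
# The classic dynamic programme with a zero floor:
#   H[i,j] = max(0, H[i-1,j-1] + s(a_i, b_j), H[i-1,j] + gap, H[i,j-1] + gap)
# Traceback starts at the maximal cell (smallest (i, j) among ties) and
# follows diagonal, then up, then left, until a zero cell.  Scoring is
# case-insensitive; 'N' scores as a mismatch against everything, including
# another 'N' — a conservative choice so runs of N never anchor alignments.

#' Scoring scheme for local alignment
#'
#' @param match score for identical bases (> 0, default 3).
#' @param mismatch score for differing bases (<= 0, default -3).
#' @param gap linear penalty per gapped position (< 0, default -2).
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 3L, mismatch = -3L, gap = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap < 0)
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap = as.numeric(gap)), class = "scoring_scheme")
}

#' Smith-Waterman local alignment
#'
#' Returns a maximal-scoring local alignment of `query` against `target`
#' under a match/mismatch/linear-gap scheme.  The score is always >= 0 and
#' is 0 exactly when no positive-scoring alignment exists (the alignment is
#' then empty).
#'
#' @param query,target non-empty sequence strings.
#' @param scheme a [scoring_scheme()].
#' @return a list of class `local_alignment`: `score`, 0-based half-open
#'   coordinates `query_start`, `query_end`, `target_start`, `target_end`,
#'   the gapped strings `aligned_query` and `aligned_target`, and a
#'   CIGAR-like string `cigar` (`M`/`I`/`D` run-length encoded, insertions
#'   relative to the target).
#' @examples
#' smith_waterman("TGTTACGG", "GGTTGACTA", scoring_scheme(3, -3, -2))
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(target)) {
    stop("query and target must be non-empty", call. = FALSE)
  }
  a <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  sub_score <- function(x, y) {
    ifelse(x == y & x != "N", scheme$match, scheme$mismatch)
  }
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    srow <- sub_score(a[i], b)
    prev <- H[i, ]
    cur <- numeric(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(0,
                         prev[j] + srow[j],
                         prev[j + 1L] + scheme$gap,
                         cur[j] + scheme$gap)
    }
    H[i + 1L, ] <- cur
  }
  best <- max(H)
  if (best <= 0) {
    return(structure(list(
      score = 0, query_start = 0L, query_end = 0L,
      target_start = 0L, target_end = 0L,
      aligned_query = "", aligned_target = "", cigar = ""
    ), class = "local_alignment"))
  }
  # smallest (i, j) among maximal cells
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1] - 1L; j <- hits[1, 2] - 1L
  end_i <- i; end_j <- j
  aq <- character(0); at <- character(0); ops <- character(0)
  while (i > 0 || j > 0) {
    h <- H[i + 1L, j + 1L]
    if (h == 0) break
    if (i > 0 && j > 0 &&
        h == H[i, j] + sub_score(a[i], b[j])) {
      aq <- c(a[i], aq); at <- c(b[j], at); ops <- c("M", ops)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && h == H[i, j + 1L] + scheme$gap) {
      aq <- c(a[i], aq); at <- c("-", at); ops <- c("I", ops)
      i <- i - 1L
    } else if (j > 0 && h == H[i + 1L, j] + scheme$gap) {
      aq <- c("-", aq); at <- c(b[j], at); ops <- c("D", ops)
      j <- j - 1L
    } else {
      stop("internal error: broken traceback", call. = FALSE)
    }
  }
  r <- rle(ops)
  structure(list(
    score = best,
    query_start = i, query_end = end_i,
    target_start = j, target_end = end_j,
    aligned_query = paste(aq, collapse = ""),
    aligned_target = paste(at, collapse = ""),
    cigar = paste0(r$lengths, r$values, collapse = "")
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("Local alignment, score ", x$score, "\n", sep = "")
  if (nzchar(x$aligned_query)) {
    marks <- ifelse(strsplit(x$aligned_query, "")[[1]] ==
                      strsplit(x$aligned_target, "")[[1]], "|", " ")
    cat("query  ", x$query_start, " ", x$aligned_query, "\n",
        "        ", paste(marks, collapse = ""), "\n",
        "target ", x$target_start, " ", x$aligned_target, "\n", sep = "")
  }
  invisible(x)
}

#' Align a query against every target in a set
#'
#' Runs [smith_waterman()] of the query (and, with `search_reverse`, of its
#' reverse complement) against each target record, keeping the better
#' orientation, and reports alignments scoring at least `min_score`.
#'
#' @param query a one-row [seq_records()] table or a sequence string.
#' @param targets a [seq_records()] table.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum reportable score (default 1, i.e. any non-empty
#'   alignment).
#' @param search_reverse also try the reverse-complemented query.
#' @return a data frame: `target`, `strand`, `score`, `target_start`,
#'   `target_end`, `query_start`, `query_end`, `cigar`, plus the aligned
#'   strings; one row per reported target.
#' @export
align_file <- function(query, targets, scheme = scoring_scheme(),
                       min_score = 1, search_reverse = TRUE) {
  if (inherits(query, "data.frame")) query <- query$sequence[1]
  qrc <- if (search_reverse) suppressWarnings(reverse_complement(query))
         else NULL
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    aln <- smith_waterman(query, targets$sequence[i], scheme)
    strand <- "+"
    if (!is.null(qrc)) {
      aln_r <- smith_waterman(qrc, targets$sequence[i], scheme)
      if (aln_r$score > aln$score) { aln <- aln_r; strand <- "-" }
    }
    if (aln$score >= min_score) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = targets$name[i], strand = strand, score = aln$score,
        target_start = aln$target_start, target_end = aln$target_end,
        query_start = aln$query_start, query_end = aln$query_end,
        cigar = aln$cigar,
        aligned_query = aln$aligned_query,
        aligned_target = aln$aligned_target,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(target = character(0), strand = character(0),
                      score = numeric(0), target_start = integer(0),
                      target_end = integer(0), query_start = integer(0),
                      query_end = integer(0), cigar = character(0),
                      aligned_query = character(0),
                      aligned_target = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
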