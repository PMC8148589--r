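#' Construct a table of sequence records
#'
#' A `seq_tbl` is the universal unit flowing through every operation in the
#' package: a data frame with one row per sequence record and columns
#' `name` (first whitespace-delimited token of the header), `comment`
#' (remainder of the header, `""` when absent), `sequence` (ASCII letters,
#' case preserved) and `quality` (same length as `sequence`, or `NA` for
#' FASTA records).
#'
#' @param name character vector of record identifiers (no whitespace).
#' @param sequence character vector of sequences; must be non-empty strings.
#' @param comment character vector of header comments (recycled, default `""`).
#' @param quality character vector of Phred-encoded quality strings or `NA`
#'   (recycled, default `NA`). When present, each must have the same number
#'   of characters as the corresponding sequence.
#' @return a data frame of class `seq_tbl`.
#' @examples
#' seq_records("r1", "ACGT", quality = "IIII")
#' @export
seq_records <- function(name, sequence, comment = "", quality = NA_character_) {
  n <- length(sequence)
  name <- as.character(name)
  sequence <- as.character(sequence)
  comment <- rep_len(as.character(comment), n)
  quality <- rep_len(as.character(quality), n)
  if (length(name) != n) {
    stop("`name` and `sequence` must have the same length", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", name))) {
    stop("record names must not contain whitespace", call. = FALSE)
  }
  if (n > 0 && any(!nzchar(sequence))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  has_q <- !is.na(quality)
  bad <- has_q & nchar(quality) != nchar(sequence)
  if (any(bad)) {
    stop(
      "quality length differs from sequence length for record '",
      name[which(bad)[1]], "'",
      call. = FALSE
    )
  }
  structure(
    data.frame(
      name = name, comment = comment, sequence = sequence, quality = quality,
      stringsAsFactors = FALSE
    ),
    class = c("seq_tbl", "data.frame")
  )
}

#' @export
print.seq_tbl <- function(x, n = 10L, ...) {
  cat("# seq_tbl: ", nrow(x), " record", if (nrow(x) != 1) "s", sep = "")
  if (nrow(x) > 0) {
    fq <- sum(!is.na(x$quality))
    cat(" (", fq, " with quality)", sep = "")
  }
  cat("\n")
  if (nrow(x) > 0) {
    show <- utils::head(x, n)
    show$sequence <- ifelse(
      nchar(show$sequence) > 40,
      paste0(substr(show$sequence, 1, 37), "..."),
      show$sequence
    )
    show$quality <- ifelse(
      is.na(show$quality), NA_character_,
      ifelse(nchar(show$quality) > 40,
             paste0(substr(show$quality, 1, 37), "..."),
             show$quality)
    )
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > n) cat("# ... and ", nrow(x) - n, " more\n", sep = "")
  }
  invisible(x)
}

# internal: full header line (name + comment) for each record
seq_headers <- function(records) {
  ifelse(
    nzchar(records$comment),
    paste(records$name, records$comment),
    records$name
  )
}

# internal: coerce a data.frame with the right columns into a seq_tbl
as_seq_tbl <- function(df) {
  seq_records(df$name, df$sequence,
              comment = if (is.null(df$comment)) "" else df$comment,
              quality = if (is.null(df$quality)) NA_character_ else df$quality)
}

# internal: empty record table
empty_seq_tbl <- function() {
  seq_records(character(0), character(0), character(0), character(0))
}
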