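# Reading and writing FASTA/FASTQ, format autodetection, mate-path inference.
#
# Parsing follows the permissive line-based model used by the classic
# kseq-style readers: FASTA sequences may span any number of lines, and the
# legacy "Sanger FASTQ" dialect is supported, where both the sequence and the
# quality string of one record may span several lines.  A '@' at the start of
# a quality continuation line is never misread as a new record: quality lines
# are consumed until the quality is as long as the sequence.

# gzip magic bytes 0x1f 0x8b
is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Read all lines of a possibly gzip-compressed file; "-" means stdin.
# Compression is detected from the magic bytes, never from the extension.
read_lines_auto <- function(path) {
  if (identical(path, "-")) {
    return(readLines(file("stdin")))
  }
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  con <- if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Detect sequence file format from its first bytes
#'
#' @param first_bytes a character scalar holding the beginning of the file
#'   (after any gzip decompression); leading blank characters are skipped.
#' @return `"fasta"` if the first non-blank character is `>`, `"fastq"` if it
#'   is `@`; any other character is an error.
#' @examples
#' detect_format(">chr1 some assembly")
#' detect_format("@read/1")
#' @export
detect_format <- function(first_bytes) {
  stripped <- sub("^[[:space:]]*", "", paste(first_bytes, collapse = "\n"))
  if (!nzchar(stripped)) {
    stop("cannot detect format: no non-blank bytes", call. = FALSE)
  }
  ch <- substr(stripped, 1, 1)
  if (ch == ">") "fasta" else if (ch == "@") "fastq" else
    stop("unrecognized format: first character is '", ch,
         "', expected '>' or '@'", call. = FALSE)
}

# Parse a character vector of lines into a seq_tbl.  `source` only labels
# error messages.
parse_fastx_lines <- function(lines, source = "<input>") {
  # tolerate CRLF input
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(lines))
  if (length(nonblank) == 0L) {
    warning("'", source, "' contains no records", call. = FALSE)
    return(empty_seq_tbl())
  }
  fmt <- detect_format(lines[nonblank[1]])
  lines <- lines[nonblank[1]:length(lines)]
  if (fmt == "fasta") parse_fasta_lines(lines, source)
  else parse_fastq_lines(lines, source)
}

parse_fasta_lines <- function(lines, source) {
  is_header <- startsWith(lines, ">")
  idx <- cumsum(is_header)
  if (any(idx == 0 & nzchar(lines))) {
    stop("'", source, "': sequence data before the first '>' header",
         call. = FALSE)
  }
  headers <- sub("^>", "", lines[is_header])
  body <- lines[!is_header]
  seqs <- vapply(
    split(body, factor(idx[!is_header], levels = seq_along(headers))),
    paste0, character(1), collapse = ""
  )
  seqs <- gsub("[[:space:]]", "", seqs)
  if (any(!nzchar(seqs))) {
    bad <- headers[which(!nzchar(seqs))[1]]
    stop("'", source, "': record '", sub("\\s.*", "", bad),
         "' has an empty sequence", call. = FALSE)
  }
  nm <- sub("\\s.*$", "", headers)
  cm <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(nm, seqs, comment = cm)
}

parse_fastq_lines <- function(lines, source) {
  n <- length(lines)
  # fast path: canonical 4-line records
  if (n %% 4L == 0L) {
    h <- lines[seq(1L, n, by = 4L)]
    s <- lines[seq(2L, n, by = 4L)]
    p <- lines[seq(3L, n, by = 4L)]
    q <- lines[seq(4L, n, by = 4L)]
    if (all(startsWith(h, "@")) && all(startsWith(p, "+")) &&
        all(nchar(q) == nchar(s)) && all(!startsWith(s, "+"))) {
      headers <- sub("^@", "", h)
      nm <- sub("\\s.*$", "", headers)
      cm <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
      return(seq_records(nm, s, comment = cm, quality = q))
    }
  }
  # general path: multi-line Sanger FASTQ state machine
  names <- character(0); comments <- character(0)
  seqs <- character(0); quals <- character(0)
  i <- 1L
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "@")) {
      stop("'", source, "': expected '@' header at line ", i, call. = FALSE)
    }
    header <- sub("^@", "", lines[i])
    nm <- sub("\\s.*$", "", header)
    i <- i + 1L
    seq_parts <- character(0)
    while (i <= n && !startsWith(lines[i], "+")) {
      seq_parts <- c(seq_parts, lines[i])
      i <- i + 1L
    }
    if (i > n) {
      stop("'", source, "': record '", nm,
           "' is truncated (no '+' separator)", call. = FALSE)
    }
    i <- i + 1L  # skip '+' line
    seq <- paste0(seq_parts, collapse = "")
    slen <- nchar(seq)
    qual <- ""
    # quality lines are consumed by length, so '@' here is never a new record
    while (nchar(qual) < slen && i <= n) {
      qual <- paste0(qual, lines[i])
      i <- i + 1L
    }
    if (nchar(qual) != slen) {
      stop("'", source, "': record '", nm, "' is truncated (quality has ",
           nchar(qual), " characters, sequence has ", slen, ")",
           call. = FALSE)
    }
    names <- c(names, nm)
    comments <- c(comments,
                  if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else "")
    seqs <- c(seqs, seq)
    quals <- c(quals, qual)
  }
  seq_records(names, seqs, comment = comments, quality = quals)
}

#' Read a FASTA or FASTQ file
#'
#' Reads plain or gzip-compressed input (compression detected from the gzip
#' magic bytes, not the file name), autodetecting FASTA vs FASTQ from the
#' first non-blank character.  FASTA sequences may span multiple lines, and
#' the legacy multi-line "Sanger FASTQ" dialect is parsed correctly: quality
#' lines are consumed until the quality is as long as the sequence, so a
#' quality continuation line starting with `@` is not mistaken for a header.
#'
#' @param path path to a FASTA/FASTQ file, or `"-"` for standard input.
#' @return a [seq_records()] table; FASTA records have `NA` quality.
#' @seealso [write_seqs()], [detect_format()]
#' @export
read_seqs <- function(path) {
  parse_fastx_lines(read_lines_auto(path), source = path)
}

#' Write records to a FASTA or FASTQ file
#'
#' FASTA is written unwrapped (header line plus a single sequence line)
#' unless `line_width` is given; FASTQ is always written as exactly four
#' lines per record.  Output is gzip-compressed when `path` ends in `.gz`.
#' Line endings are always LF.
#'
#' @param records a [seq_records()] table.
#' @param path output path, or `"-"` for standard output.
#' @param format `"fasta"` or `"fastq"`; `"auto"` (default) writes FASTQ when
#'   every record has a quality string and FASTA otherwise.
#' @param line_width optional positive integer: wrap FASTA sequence lines at
#'   this width. Ignored for FASTQ.
#' @return invisibly, the number of records written.
#' @export
write_seqs <- function(records, path, format = c("auto", "fasta", "fastq"),
                       line_width = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (nrow(records) > 0 && all(!is.na(records$quality)))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    miss <- is.na(records$quality)
    if (any(miss)) {
      stop("record '", records$name[which(miss)[1]],
           "' has no quality string; cannot write FASTQ", call. = FALSE)
    }
  }
  headers <- seq_headers(records)
  if (nrow(records) == 0L) {
    out <- character(0)
  } else if (format == "fasta") {
    seqs <- records$sequence
    if (!is.null(line_width)) {
      stopifnot(line_width >= 1)
      seqs <- vapply(seqs, function(s) {
        paste0(substring(s, seq(1, nchar(s), by = line_width),
                         pmin(seq(1, nchar(s), by = line_width) + line_width - 1,
                              nchar(s))),
               collapse = "\n")
      }, character(1), USE.NAMES = FALSE)
    }
    out <- paste0(">", headers, "\n", seqs)
  } else {
    out <- paste0("@", headers, "\n", records$sequence, "\n+\n",
                  records$quality)
  }
  con <- if (identical(path, "-")) stdout()
         else if (grepl("\\.gz$", path)) gzfile(path, "wb")
         else file(path, "wb")
  if (!identical(path, "-")) on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(nrow(records))
}

#' Infer the mate (R2) path of a forward (R1) read file
#'
#' Tries the naming conventions `_R1` -> `_R2`, `_1.` -> `_2.` and
#' `.1.` -> `.2.`, in that order, on the file's basename.  The returned path
#' is not checked for existence; callers do that.
#'
#' @param r1 path of the forward read file.
#' @return the inferred reverse-mate path.
#' @examples
#' infer_mate_path("sample_R1.fastq.gz")
#' @export
infer_mate_path <- function(r1) {
  base <- basename(r1)
  dir <- dirname(r1)
  tags <- list(c("_R1", "_R2"), c("_1.", "_2."), c(".1.", ".2."))
  hits <- vapply(tags, function(t) {
    lengths(regmatches(base, gregexpr(t[1], base, fixed = TRUE)))
  }, integer(1))
  n_candidates <- sum(hits > 0)
  if (n_candidates == 0L) {
    stop("cannot infer mate of '", r1, "': no _R1/_1./.1. tag found",
         call. = FALSE)
  }
  first <- which(hits > 0)[1]
  if (n_candidates > 1L || hits[first] > 1L) {
    stop("ambiguous pair naming in '", r1,
         "': more than one candidate mate tag", call. = FALSE)
  }
  out <- sub(tags[[first]][1], tags[[first]][2], base, fixed = TRUE)
  if (dir == ".") out else file.path(dir, out)
}
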