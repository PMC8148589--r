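# Record selection and transformation: head/tail with stride, grep by name
# or sequence motif, length sort, and dereplication with size-tag
# propagation plus a JSON provenance report.

#' First records of a stream, with an optional stride
#'
#' Emits the records at positions `1, (skip+2), 2*(skip+1)+1, ...` until `n`
#' records have been emitted or the input ends — so `skip = 11` extracts one
#' sequence every 12.
#'
#' @param records a [seq_records()] table.
#' @param n maximum number of records to emit.
#' @param skip records to skip between emitted ones (default 0).
#' @return the selected records, unchanged and in order.
#' @export
seq_head <- function(records, n, skip = 0L) {
  stopifnot(n >= 1L, skip >= 0L)
  idx <- seq.int(1L, nrow(records), by = skip + 1L)
  idx <- utils::head(idx, n)
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("seq_tbl", "data.frame"))
}

#' Last records of a stream
#'
#' @param records a [seq_records()] table.
#' @param n number of final records to keep (fewer if the input is shorter).
#' @return the final records in their original order.
#' @export
seq_tail <- function(records, n) {
  stopifnot(n >= 1L)
  out <- utils::tail(records, n)
  rownames(out) <- NULL
  structure(out, class = c("seq_tbl", "data.frame"))
}

#' Filter records by name and/or sequence motif
#'
#' Mimics GNU grep for sequence files: a record passes when its header
#' matches `name_query` (exact substring, or a regular expression with
#' `regex = TRUE`) and its sequence contains at least one [find_oligo()]
#' hit of `seq_query` on either strand.  Either query may be omitted; at
#' least one must be given.  Records are emitted unchanged, in order.
#'
#' @param records a [seq_records()] table.
#' @param name_query string to find in the header, or `NULL`.
#' @param seq_query IUPAC oligonucleotide to find in the sequence, or `NULL`.
#' @param regex treat `name_query` as a regular expression.
#' @param full_header match `name_query` against name + comment (default)
#'   rather than the name alone.
#' @param max_mismatches,min_match_length,search_reverse passed to
#'   [find_oligo()] for the sequence query.
#' @return the matching records.
#' @export
seq_grep <- function(records, name_query = NULL, seq_query = NULL,
                     regex = FALSE, full_header = TRUE,
                     max_mismatches = 0L, min_match_length = NULL,
                     search_reverse = TRUE) {
  if (is.null(name_query) && is.null(seq_query)) {
    stop("at least one of `name_query`, `seq_query` must be given",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(name_query)) {
    if (regex) {
      ok <- tryCatch({suppressWarnings(grepl(name_query, "")); TRUE},
                     error = function(e) FALSE)
      if (!ok) stop("invalid regular expression: '", name_query, "'",
                    call. = FALSE)
    }
    hay <- if (full_header) seq_headers(records) else records$name
    keep <- keep & grepl(name_query, hay, fixed = !regex)
  }
  if (!is.null(seq_query)) {
    mml <- if (is.null(min_match_length)) ceiling(nchar(seq_query) / 2)
           else min_match_length
    keep <- keep & vapply(records$sequence, function(s) {
      nrow(find_oligo(s, seq_query, max_mismatches = max_mismatches,
                      min_match_length = mml,
                      search_reverse = search_reverse)) > 0
    }, logical(1), USE.NAMES = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("seq_tbl", "data.frame"))
}

#' Sort records by sequence length
#'
#' A stable sort: equal-length records keep their input order.
#'
#' @param records a [seq_records()] table.
#' @param descending longest first (default).
#' @return the sorted records.
#' @export
sort_by_length <- function(records, descending = TRUE) {
  ord <- order(nchar(records$sequence), decreasing = descending)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("seq_tbl", "data.frame"))
}

#' Parse a size= multiplicity tag out of a header
#'
#' Recognizes the USEARCH/VSEARCH abundance annotation `;size=N` (also a
#' bare whitespace-separated `size=N` token, and the spaced `size = N`
#' variant) anywhere in the header.  A header without a tag has multiplicity
#' 1.
#'
#' @param header the full header string (name plus comment).
#' @return a list: `clean_name` (header with the tag removed) and `size`.
#' @examples
#' parse_size_tag("seq1;size=13")
#' @export
parse_size_tag <- function(header) {
  pat <- "(;\\s*|\\s+|^)size\\s*=\\s*([^;\\s]+)"
  m <- regexpr(pat, header, perl = TRUE)
  if (m == -1L) {
    return(list(clean_name = header, size = 1L))
  }
  tag <- regmatches(header, m)
  val <- sub(pat, "\\2", tag, perl = TRUE)
  size <- suppressWarnings(as.integer(val))
  if (is.na(size) || size < 1L || as.character(size) != val) {
    stop("malformed size tag in header '", header, "'", call. = FALSE)
  }
  clean <- sub(pat, "", header, perl = TRUE)
  clean <- sub("[;\\s]+$", "", clean, perl = TRUE)
  list(clean_name = clean, size = size)
}

#' Dereplicate sequences with abundance propagation
#'
#' Records with identical sequences (case-folded unless `case_sensitive`)
#' collapse into one representative named
#' `<first-seen clean name>;size=<total>`, where the total sums the `size=`
#' multiplicities already present on the inputs — so repeated dereplication
#' steps keep reporting the number of original reads per unique sequence.
#' Output records are FASTA (qualities are dropped) ordered by decreasing
#' size, ties by first appearance.  The accompanying report records, for
#' every unique sequence, how many copies each input file contributed.
#'
#' @param inputs a named list of [seq_records()] tables (names identify the
#'   input files), a single table, or a character vector of file paths
#'   (read with [read_seqs()]).
#' @param min_size entries with a total size below this are dropped from the
#'   output records (but still counted in the report).
#' @param case_sensitive keep `acgt` distinct from `ACGT`.
#' @return a list with `records` (the dereplicated [seq_records()] table)
#'   and `report` (a `derep_report`: `input_records`, `unique_records`, and
#'   an `entries` data frame with `name`, `size` and per-file counts in
#'   `files`).
#' @export
dereplicate <- function(inputs, min_size = 1L, case_sensitive = FALSE) {
  stopifnot(min_size >= 1L)
  if (is.character(inputs)) {
    paths <- inputs
    inputs <- lapply(paths, read_seqs)
    names(inputs) <- paths
  } else if (inherits(inputs, "data.frame")) {
    inputs <- list(input = inputs)
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- paste0("input", seq_along(inputs))
  }

  file_of <- rep(names(inputs), vapply(inputs, nrow, integer(1)))
  all <- do.call(rbind, lapply(inputs, as.data.frame))
  if (is.null(all) || nrow(all) == 0L) {
    rep <- structure(list(input_records = 0L, unique_records = 0L,
                          entries = list()), class = "derep_report")
    return(list(records = empty_seq_tbl(), report = rep))
  }
  parsed <- lapply(seq_headers(as_seq_tbl(all)), parse_size_tag)
  sizes <- vapply(parsed, `[[`, integer(1), "size")
  clean <- vapply(parsed, `[[`, character(1), "clean_name")
  key <- if (case_sensitive) all$sequence else toupper(all$sequence)

  first_idx <- which(!duplicated(key))
  uniq_keys <- key[first_idx]
  grp <- match(key, uniq_keys)
  total <- as.integer(tapply(sizes, grp, sum)[as.character(seq_along(uniq_keys))])
  per_file <- lapply(seq_along(uniq_keys), function(g) {
    i <- which(grp == g)
    tab <- tapply(sizes[i], file_of[i], sum)
    as.list(tab[order(match(names(tab), names(inputs)))])
  })

  ord <- order(-total, first_idx)
  rep_names <- sub("\\s.*$", "", clean[first_idx])
  entries <- data.frame(
    name = rep_names[ord],
    sequence = all$sequence[first_idx][ord],
    size = total[ord],
    stringsAsFactors = FALSE
  )
  entries$files <- per_file[ord]
  report <- structure(list(
    input_records = sum(sizes),
    unique_records = nrow(entries),
    entries = entries
  ), class = "derep_report")

  keep <- entries$size >= min_size
  out <- seq_records(
    name = paste0(entries$name[keep], ";size=", entries$size[keep]),
    sequence = entries$sequence[keep]
  )
  list(records = out, report = report)
}

#' Serialize a dereplication report to JSON
#'
#' Schema: `{input_records, unique_records,
#' entries: [{name, size, files: {path: count}}]}`.
#'
#' @param report the `report` element of a [dereplicate()] result.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
derep_report_json <- function(report, path = NULL) {
  entries <- lapply(seq_len(NROW(report$entries)), function(i) {
    list(name = report$entries$name[i],
         size = report$entries$size[i],
         files = report$entries$files[[i]])
  })
  obj <- list(input_records = report$input_records,
              unique_records = report$unique_records,
              entries = entries)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Parse a dereplication report back from JSON
#'
#' Inverse of [derep_report_json()]; the round trip is lossless.
#'
#' @param json a JSON string or a path to a JSON file.
#' @return a `derep_report` object.
#' @export
derep_report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  entries <- data.frame(
    name = vapply(obj$entries, `[[`, character(1), "name"),
    size = vapply(obj$entries, function(e) as.integer(e$size), integer(1)),
    stringsAsFactors = FALSE
  )
  entries$files <- lapply(obj$entries, function(e) {
    lapply(e$files, as.integer)
  })
  structure(list(
    input_records = as.integer(obj$input_records),
    unique_records = as.integer(obj$unique_records),
    entries = entries
  ), class = "derep_report")
}

#' @export
print.derep_report <- function(x, ...) {
  cat("Dereplication: ", x$input_records, " input records -> ",
      x$unique_records, " unique sequences\n", sep = "")
  invisible(x)
}
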