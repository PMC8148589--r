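# Terminal rendering of one read: the sequence, a quality track of Unicode
# block glyphs binned into four colour classes, and an arrow track marking
# oligonucleotide hits.

# quality bins: Q<6 gray, 6<=Q<15 red, 15<=Q<30 yellow, Q>=30 green
QUAL_BIN_BREAKS <- c(6L, 15L, 30L)
BLOCK_GLYPHS <- c("▁", "▃", "▅", "█")
ANSI_COLORS <- c(gray = "\033[90m", red = "\033[31m",
                 yellow = "\033[33m", green = "\033[32m")

#' Render a read with quality bars and match arrows
#'
#' Produces a small text panel: the sequence, beneath it a quality track
#' where each base's Phred score is drawn as a block glyph of increasing
#' height (four bins: gray below Q6, red to Q14, yellow to Q29, green from
#' Q30), and — when hits are supplied — an arrow track marking matched
#' positions (`>` forward strand, `<` reverse).  With `color = TRUE` the
#' quality glyphs carry ANSI colour codes.
#'
#' @param record a one-row [seq_records()] table.
#' @param oligo_hits optional [find_oligo()] result to mark.
#' @param offset Phred offset of the quality string (33 or 64).
#' @param color emit ANSI colour escapes (default `FALSE`, pipeline-safe).
#' @return a character vector of lines, invisibly printed with `cat()` by
#'   `print`.
#' @export
render_view <- function(record, oligo_hits = NULL, offset = 33L,
                        color = FALSE) {
  stopifnot(nrow(record) == 1L, offset %in% c(33L, 64L))
  len <- nchar(record$sequence)
  lines <- paste0("@", seq_headers(record))
  lines <- c(lines, record$sequence)
  if (!is.na(record$quality)) {
    q <- utf8ToInt(record$quality) - offset
    bin <- findInterval(q, QUAL_BIN_BREAKS) + 1L
    glyphs <- BLOCK_GLYPHS[bin]
    if (color) {
      cols <- names(ANSI_COLORS)[bin]
      glyphs <- paste0(ANSI_COLORS[cols], glyphs, "\033[0m")
    }
    lines <- c(lines, paste(glyphs, collapse = ""))
  }
  if (!is.null(oligo_hits) && nrow(oligo_hits) > 0) {
    track <- rep(" ", len)
    for (k in seq_len(nrow(oligo_hits))) {
      span <- seq.int(oligo_hits$position[k] + 1L,
                      oligo_hits$position[k] + oligo_hits$length[k])
      track[span] <- if (oligo_hits$strand[k] == "+") ">" else "<"
    }
    lines <- c(lines, paste(track, collapse = ""))
  }
  structure(lines, class = "view_rendering")
}

#' @export
print.view_rendering <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
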