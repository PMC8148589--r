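# Independent oracles used across the suite.  Each is deliberately written
# by a different route than the implementation it checks: literal IUPAC
# expansion + fixed-string search for the matcher, sort/cumulate/scan for
# N50, Biostrings for translation and alignment scores.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# expand an IUPAC string into every concrete ACGT sequence it denotes
expand_iupac <- function(query) {
  sets <- IUPAC_SETS[strsplit(toupper(query), "")[[1]]]
  stopifnot(!anyNA(names(sets)))
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

# 0-based start positions of exact full-length matches of an IUPAC query on
# the forward strand of a plain ACGT target: expand, then fixed-string
# search each expansion (lookahead so overlapping occurrences all count)
oligo_oracle_positions <- function(target, query) {
  hits <- integer(0)
  for (concrete in expand_iupac(query)) {
    m <- gregexpr(paste0("(?=", concrete, ")"), target, perl = TRUE)[[1]]
    if (m[1] != -1L) hits <- c(hits, as.integer(m) - 1L)
  }
  sort(unique(hits))
}

# brute-force N50: sort decreasing, cumulate, scan
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- 0
  for (l in s) {
    cum <- cum + l
    if (cum >= sum(lengths) / 2) return(l)
  }
}

aun_oracle <- function(lengths) sum(as.numeric(lengths)^2) / sum(lengths)

# six-frame ORF enumeration via the Biostrings genetic code, coordinates
# mapped to the forward strand by hand
orf_oracle <- function(seq, min_aa, require_start = FALSE,
                       require_stop = FALSE) {
  code <- Biostrings::GENETIC_CODE
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- list()
  for (fr in c("+1", "+2", "+3", "-1", "-2", "-3")) {
    f <- as.integer(sub("\\+", "", fr))
    s <- if (f > 0) toupper(seq) else toupper(rc)
    off <- abs(f) - 1L
    nc <- (nchar(s) - off) %/% 3L
    if (nc < 1L) next
    starts <- off + 3L * (seq_len(nc) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "?"
    run_start <- NULL
    for (k in seq_len(nc + 1L)) {
      breaker <- k > nc || aa[k] %in% c("*", "?")
      if (!breaker && is.null(run_start)) run_start <- k
      if (breaker && !is.null(run_start)) {
        a <- run_start; b <- k - 1L
        run_start <- NULL
        stopped <- k <= nc && aa[k] == "*"
        if (require_stop && !stopped) next
        if (require_start) {
          mpos <- which(codons[a:b] == "ATG")
          if (length(mpos) == 0L) next
          a <- a + mpos[1] - 1L
        }
        if (b - a + 1L < min_aa) next
        s_t <- off + 3L * (a - 1L); e_t <- off + 3L * b
        rows[[length(rows) + 1L]] <- data.frame(
          frame = fr,
          nt_start = if (f > 0) s_t else L - e_t,
          nt_end = if (f > 0) e_t else L - s_t,
          peptide = paste(aa[a:b], collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(frame = character(0), nt_start = integer(0),
                      nt_end = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$frame, c("+1", "+2", "+3", "-1", "-2", "-3")),
                   out$nt_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# local-alignment score via Biostrings (linear gap = opening 0, extension
# |gap|); an established implementation, independent of ours
sw_score_oracle <- function(query, target, match, mismatch, gap) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    query, target, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(gap), scoreOnly = TRUE)
}

# recompute an alignment's score from its two gapped strings
score_from_alignment <- function(aln, scheme) {
  if (!nzchar(aln$aligned_query)) return(0)
  a <- strsplit(aln$aligned_query, "")[[1]]
  b <- strsplit(aln$aligned_target, "")[[1]]
  sum(ifelse(a == "-" | b == "-", scheme$gap,
             ifelse(a == b & a != "N", scheme$match, scheme$mismatch)))
}

random_acgt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_iupac <- function(len, n_ambiguous = 2L) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  amb <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                min(n_ambiguous, len), replace = TRUE)
  chars[sample(len, length(amb))] <- amb
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
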