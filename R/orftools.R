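# Six-frame translation and open-reading-frame extraction, with optional
# joining of paired-end reads beforehand.
#
# Translation uses the standard genetic code.  Degenerate codons (IUPAC
# codes) are expanded: when every expansion encodes the same amino acid the
# codon translates to it (e.g. GCN -> A); when the expansions disagree but
# none is a stop, the codon is 'X'; when some expansions are stops and some
# are not, the codon is undeterminable ('?'  internally) and breaks ORF
# runs — an all-N sequence therefore yields no ORFs.

STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

IUPAC_EXPANSION <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# translate one (possibly degenerate) codon; "?" = could be stop or not
translate_codon <- function(codon) {
  aa <- STANDARD_CODE[codon]
  if (!is.na(aa)) return(unname(aa))
  sets <- IUPAC_EXPANSION[strsplit(codon, "", fixed = TRUE)[[1]]]
  if (anyNA(sets)) return("?")
  combos <- expand.grid(strsplit(sets[1], "")[[1]],
                        strsplit(sets[2], "")[[1]],
                        strsplit(sets[3], "")[[1]],
                        stringsAsFactors = FALSE)
  aas <- unique(unname(STANDARD_CODE[paste0(combos[[1]], combos[[2]],
                                            combos[[3]])]))
  if (length(aas) == 1L) return(aas)
  if ("*" %in% aas) return("?")
  "X"
}

# memoised degenerate-codon table, filled on demand
.codon_cache <- new.env(parent = emptyenv())

codon_aa <- function(codons) {
  out <- STANDARD_CODE[codons]
  miss <- which(is.na(out))
  for (i in miss) {
    key <- codons[i]
    if (is.null(.codon_cache[[key]])) {
      .codon_cache[[key]] <- translate_codon(key)
    }
    out[i] <- .codon_cache[[key]]
  }
  unname(out)
}

#' Translate DNA in a given reading frame
#'
#' Frames `+1/+2/+3` read from offsets 0/1/2 of the forward strand; `-1/-2/-3`
#' read the same offsets of the reverse complement.  The trailing partial
#' codon is dropped, stop codons are `*`, and degenerate codons are resolved
#' by IUPAC expansion: unanimous codons translate normally (`GCN` -> `A`),
#' ambiguous non-stop codons give `X`, and codons that might or might not be
#' stops give `X` as well.
#'
#' @param seq a DNA string.
#' @param frame one of `"+1","+2","+3","-1","-2","-3"` (or integer
#'   1..3 / -1..-3).
#' @return the protein string.
#' @examples
#' translate_dna("ATGAAATAA")      # "MK*"
#' translate_dna("ATGAAATAA", -1)  # frame -1
#' @export
translate_dna <- function(seq, frame = "+1") {
  codons <- frame_codons(seq, frame)
  aa <- codon_aa(codons)
  aa[aa == "?"] <- "X"
  paste(aa, collapse = "")
}

# normalize frame spec to integer in {1,2,3,-1,-2,-3}
norm_frame <- function(frame) {
  f <- if (is.character(frame)) as.integer(sub("^\\+", "", frame))
       else as.integer(frame)
  if (is.na(f) || !(abs(f) %in% 1:3)) {
    stop("frame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  }
  f
}

# codon strings of a frame (empty character vector if none fit)
frame_codons <- function(seq, frame) {
  f <- norm_frame(frame)
  s <- toupper(seq)
  if (f < 0) s <- toupper(suppressWarnings(reverse_complement(s)))
  off <- abs(f) - 1L
  n_codons <- (nchar(s) - off) %/% 3L
  if (n_codons < 1L) return(character(0))
  starts <- off + 3L * (seq_len(n_codons) - 1L) + 1L
  substring(s, starts, starts + 2L)
}

#' Extract open reading frames from all six frames
#'
#' An ORF is a maximal run of codons between stop codons (and sequence
#' ends) in one frame; with `require_start` it begins at the first `ATG` of
#' the run, with `require_stop` it must be terminated by an actual stop
#' codon.  The stop codon itself is not part of the reported span or the
#' peptide.  Codons whose IUPAC expansions include both stop and non-stop
#' readings break runs (they cannot be trusted either way).  Coordinates
#' are 0-based half-open on the forward strand for all frames.
#'
#' @param record a one-row [seq_records()] table or a sequence string.
#' @param min_aa minimum peptide length in amino acids (default 25).
#' @param require_start ORFs must begin with ATG (default `FALSE`).
#' @param require_stop ORFs must end at a stop codon (default `FALSE`).
#' @return a data frame with columns `source_name`, `frame`, `nt_start`,
#'   `nt_end`, `nt_length`, `peptide`, sorted by frame then start.
#' @export
find_orfs <- function(record, min_aa = 25L, require_start = FALSE,
                      require_stop = FALSE) {
  if (inherits(record, "data.frame")) {
    stopifnot(nrow(record) == 1L)
    name <- record$name
    seq <- record$sequence
  } else {
    name <- "seq"
    seq <- record
  }
  stopifnot(min_aa >= 1L)
  L <- nchar(seq)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- list()
  for (fr in frames) {
    f <- norm_frame(fr)
    codons <- frame_codons(seq, fr)
    if (length(codons) == 0L) next
    aa <- codon_aa(codons)
    breaker <- aa %in% c("*", "?")
    # maximal runs of non-breaker codons
    r <- rle(breaker)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      a <- starts[k]; b <- ends[k]
      stopped <- b < length(codons) && aa[b + 1L] == "*"
      if (require_stop && !stopped) next
      if (require_start) {
        m <- which(codons[a:b] == "ATG")
        if (length(m) == 0L) next
        a <- a + m[1] - 1L
      }
      n_aa <- b - a + 1L
      if (n_aa < min_aa) next
      off <- abs(f) - 1L
      # codon positions on the translated strand, 0-based
      s_t <- off + 3L * (a - 1L)
      e_t <- off + 3L * b
      if (f > 0) {
        nt_start <- s_t; nt_end <- e_t
      } else {
        nt_start <- L - e_t; nt_end <- L - s_t
      }
      out[[length(out) + 1L]] <- data.frame(
        source_name = name, frame = fr,
        nt_start = nt_start, nt_end = nt_end,
        nt_length = e_t - s_t,
        peptide = paste(aa[a:b], collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(source_name = character(0), frame = character(0),
                      nt_start = integer(0), nt_end = integer(0),
                      nt_length = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$frame, frames), res$nt_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Join a read pair into a single fragment
#'
#' Reverse-complements the reverse mate, then slides it along the forward
#' mate looking for the overlap (of at least `min_overlap` bases) with the
#' fewest mismatches; ties prefer the longest overlap.  If the best
#' overlap's mismatch fraction is within `max_mismatch_fraction`, the reads
#' are merged — each overlap base taken from whichever mate has the higher
#' quality there (from the forward mate when qualities are absent).
#' Otherwise the mates are concatenated with a 10-base `N` spacer so both
#' are still scanned downstream (e.g. for ORFs).
#'
#' @param r1,r2 one-row [seq_records()] tables (forward and reverse mate).
#' @param min_overlap minimum overlap length to accept a merge (default 10).
#' @param max_mismatch_fraction maximum fraction of mismatching overlap
#'   positions (default 0.1).
#' @return a one-row [seq_records()] table for the joined fragment; the
#'   attribute `"joined"` is `TRUE` for a real overlap merge, `FALSE` for
#'   the spacer fallback.
#' @export
join_pairs <- function(r1, r2, min_overlap = 10L,
                       max_mismatch_fraction = 0.1) {
  stopifnot(nrow(r1) == 1L, nrow(r2) == 1L,
            nzchar(r1$sequence), nzchar(r2$sequence))
  s1 <- r1$sequence
  s2 <- suppressWarnings(reverse_complement(r2$sequence))
  q1 <- r1$quality
  q2 <- if (is.na(r2$quality)) NA_character_ else
    paste(rev(strsplit(r2$quality, "", fixed = TRUE)[[1]]), collapse = "")
  n1 <- nchar(s1); n2 <- nchar(s2)
  c1 <- strsplit(toupper(s1), "", fixed = TRUE)[[1]]
  c2 <- strsplit(toupper(s2), "", fixed = TRUE)[[1]]

  best_ov <- 0L; best_mm <- Inf
  ov_range <- if (min(n1, n2) >= min_overlap)
    seq.int(min(n1, n2), min_overlap) else integer(0)
  for (ov in ov_range) {
    mm <- sum(c1[(n1 - ov + 1L):n1] != c2[seq_len(ov)])
    if (mm < best_mm) { best_mm <- mm; best_ov <- ov }
  }
  name <- strip_mate_token(r1$name)
  if (best_ov >= min_overlap &&
      best_mm / best_ov <= max_mismatch_fraction) {
    ov <- best_ov
    head1 <- substr(s1, 1L, n1 - ov)
    tail2 <- substr(s2, ov + 1L, n2)
    ov1 <- substr(s1, n1 - ov + 1L, n1)
    ov2 <- substr(s2, 1L, ov)
    if (!is.na(q1) && !is.na(q2)) {
      qv1 <- utf8ToInt(substr(q1, n1 - ov + 1L, n1))
      qv2 <- utf8ToInt(substr(q2, 1L, ov))
      pick2 <- qv2 > qv1
      ovc <- strsplit(ov1, "", fixed = TRUE)[[1]]
      ovc[pick2] <- strsplit(ov2, "", fixed = TRUE)[[1]][pick2]
      ovq <- intToUtf8(pmax(qv1, qv2))
      merged_q <- paste0(substr(q1, 1L, n1 - ov), ovq,
                         substr(q2, ov + 1L, n2))
      merged_s <- paste0(head1, paste(ovc, collapse = ""), tail2)
      out <- seq_records(name, merged_s, quality = merged_q)
    } else {
      merged_s <- paste0(head1, ov1, tail2)
      out <- seq_records(name, merged_s)
    }
    attr(out, "joined") <- TRUE
  } else {
    spacer <- strrep("N", 10L)
    merged_s <- paste0(s1, spacer, s2)
    if (!is.na(q1) && !is.na(q2)) {
      out <- seq_records(name, merged_s,
                         quality = paste0(q1, strrep("!", 10L), q2))
    } else {
      out <- seq_records(name, merged_s)
    }
    attr(out, "joined") <- FALSE
  }
  out
}
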