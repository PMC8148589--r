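test_that("reverse complement follows the IUPAC table and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("RYN"), "NRY")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("acgtn"), "nacgt")  # case preserved
  alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
  expect_equal(reverse_complement(reverse_complement(alphabet)), alphabet)
  set.seed(21)
  strs <- vapply(1:200, function(i) {
    paste(sample(alphabet, sample(1:50, 1), replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(reverse_complement(reverse_complement(strs)), strs)
  expect_warning(out <- reverse_complement("AXG"), "non-IUPAC")
  expect_equal(out, "CNT")
  expect_error(reverse_complement("AXG", strict = TRUE), "non-IUPAC")
})

test_that("IUPAC compatibility is set intersection, checked by expansion", {
  expect_true(iupac_compatible("N", "A"))
  expect_false(iupac_compatible("R", "C"))
  expect_true(iupac_compatible("S", "G"))
  expect_true(iupac_compatible("r", "a"))  # case-insensitive
  codes <- names(IUPAC_SETS)
  for (p in codes) for (t in codes) {
    expect_equal(
      iupac_compatible(p, t),
      length(intersect(IUPAC_SETS[[p]], IUPAC_SETS[[t]])) > 0,
      info = paste(p, t)
    )
  }
  expect_error(iupac_compatible("X", "A", strict = TRUE), "non-IUPAC")
})

test_that("find_oligo locates degenerate queries as the expansion oracle does", {
  hit <- find_oligo("GGAGTGG", "ARY", min_match_length = 3,
                    search_reverse = FALSE)
  expect_equal(hit$position, 2L)
  expect_equal(hit$strand, "+")
  expect_false(hit$partial[1])

  set.seed(22)
  for (i in 1:60) {
    target <- random_acgt(sample(20:200, 1))
    query <- random_iupac(sample(1:8, 1), sample(0:2, 1))
    mine <- find_oligo(target, query, max_mismatches = 0,
                       min_match_length = nchar(query),
                       search_reverse = FALSE)
    expect_equal(mine$position, oligo_oracle_positions(target, query),
                 info = paste(target, query))
  }
})

test_that("reverse-strand hits mirror forward hits of the rc query", {
  rc_hit <- find_oligo("AAAA", "TTTT", max_mismatches = 0,
                       min_match_length = 4, search_reverse = TRUE)
  expect_equal(rc_hit$strand, "-")
  expect_equal(rc_hit$position, 0L)
  set.seed(23)
  for (i in 1:40) {
    target <- random_acgt(sample(20:150, 1))
    query <- random_iupac(sample(2:8, 1), 1)
    both <- find_oligo(target, query, min_match_length = nchar(query),
                       search_reverse = TRUE)
    fwd_of_rc <- find_oligo(target, reverse_complement(query),
                            min_match_length = nchar(query),
                            search_reverse = FALSE)
    expect_equal(both$position[both$strand == "-"], fwd_of_rc$position)
  }
})

test_that("partial matches are query overhangs at target ends only", {
  # query CCCCAA: its 4-base prefix CCCC overhangs the right target end
  hits <- find_oligo("GGGGCCCC", "CCCCAA", max_mismatches = 0,
                     min_match_length = 4, search_reverse = FALSE)
  part <- hits[hits$partial, , drop = FALSE]
  expect_equal(part$position, 4L)
  expect_equal(part$length, 4L)
  # internal occurrences shorter than the query are not reported
  none <- find_oligo("GGCCCCGG", "CCCCAA", max_mismatches = 0,
                     min_match_length = 4, search_reverse = FALSE)
  expect_false(any(none$partial & none$position > 0 &
                     none$position + none$length < 8))
  expect_error(find_oligo("ACGT", "NNNNNNNN", min_match_length = 9),
               "min_match_length")
  expect_error(find_oligo("ACGT", ""), "non-empty")
})

test_that("mismatch tolerance counts incompatible positions in the overlap", {
  # ACGT vs AGGT: one incompatible position
  expect_equal(nrow(find_oligo("AAAGGTAA", "ACGT", max_mismatches = 0,
                               min_match_length = 4,
                               search_reverse = FALSE)), 0L)
  one <- find_oligo("AAAGGTAA", "ACGT", max_mismatches = 1,
                    min_match_length = 4, search_reverse = FALSE)
  expect_true(any(one$position == 2 & one$mismatches == 1))
})

test_that("mask_primers replaces covered bases and nothing else", {
  rec <- seq_records("r", "ACGTACGT", quality = "IIIIIIII")
  masked <- mask_primers(rec, "ACGT", min_match_length = 4)
  expect_equal(masked$sequence, "NNNNNNNN")
  expect_equal(masked$quality, "IIIIIIII")
  expect_equal(masked$name, "r")

  untouched <- mask_primers(seq_records("r", "GGGGGGGG"), "ACTT",
                            min_match_length = 4)
  expect_equal(untouched$sequence, "GGGGGGGG")
  expect_error(mask_primers(rec, character(0)), "at least one")

  # masking never changes lengths
  set.seed(24)
  for (i in 1:20) {
    r <- seq_records("r", random_acgt(60))
    m <- mask_primers(r, random_iupac(6, 1))
    expect_equal(nchar(m$sequence), 60L)
  }
})
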