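test_that("head emits strided records up to the limit", {
  recs <- sim_records(10, read_length = 20, seed = 51)
  expect_equal(seq_head(recs, 2, skip = 2)$name, recs$name[c(1, 4)])
  expect_equal(nrow(seq_head(sim_records(3, read_length = 10, seed = 1),
                             5)), 3L)
  big <- sim_records(1200, read_length = 10, seed = 52)
  sel <- seq_head(big, 100, skip = 11)
  expect_equal(nrow(sel), 100L)
  expect_equal(sel$name, big$name[seq(1, by = 12, length.out = 100)])
})

test_that("tail keeps the final records in order", {
  recs <- seq_records(c("a", "b", "c", "d"), c("A", "C", "G", "T"))
  expect_equal(seq_tail(recs, 2)$name, c("c", "d"))
  expect_equal(seq_tail(recs, 10)$name, recs$name)
  expect_identical(seq_tail(seq_head(recs, 1), 1), seq_head(recs, 1))
})

test_that("grep filters by name, regex, and oligo — as a conjunction", {
  recs <- seq_records(c("read_1", "read_2", "other"),
                      c("GGAGTGG", "CCCCCC", "GGAGTGG"))
  expect_equal(seq_grep(recs, name_query = "read_1")$name, "read_1")
  expect_equal(seq_grep(recs, name_query = "^read_[0-9]+$",
                        regex = TRUE)$name, c("read_1", "read_2"))
  expect_equal(seq_grep(recs, seq_query = "ARY",
                        min_match_length = 3)$name, c("read_1", "other"))
  # conjunction with disjoint matches is empty
  expect_equal(nrow(seq_grep(recs, name_query = "read_2",
                             seq_query = "ARY", min_match_length = 3)), 0L)
  expect_error(seq_grep(recs), "at least one")
  expect_error(seq_grep(recs, name_query = "([", regex = TRUE),
               "regular expression")
  # output records are unchanged
  out <- seq_grep(recs, name_query = "read")
  expect_identical(out, recs[1:2, ] |> (\(x) {rownames(x) <- NULL;
    structure(x, class = c("seq_tbl", "data.frame"))})())
})

test_that("length sort is stable and idempotent", {
  recs <- seq_records(c("a", "b", "c", "d"),
                      c("AAA", "C", "GG", "TT"))
  desc <- sort_by_length(recs)
  expect_equal(desc$name, c("a", "c", "d", "b"))  # ties keep input order
  asc <- sort_by_length(recs, descending = FALSE)
  expect_equal(asc$name, c("b", "c", "d", "a"))
  expect_identical(sort_by_length(desc), desc)
})

test_that("size tags parse in all accepted dialects", {
  expect_equal(parse_size_tag("seq1;size=13"),
               list(clean_name = "seq1", size = 13L))
  expect_equal(parse_size_tag("seq1"), list(clean_name = "seq1", size = 1L))
  expect_equal(parse_size_tag("seq1 size=4 extra")$size, 4L)
  expect_equal(parse_size_tag("seq1 size = 9")$size, 9L)  # spaced variant
  expect_equal(parse_size_tag("seq1;size=2;")$clean_name, "seq1")
  expect_error(parse_size_tag("seq1;size=0"), "malformed")
  expect_error(parse_size_tag("seq1;size=abc"), "malformed")
})

test_that("dereplication collapses duplicates with provenance", {
  recs <- seq_records(paste0("r", 1:5),
                      c("AAAA", "AAAA", "CCCC", "AAAA", "CCCC"))
  res <- dereplicate(recs)
  expect_equal(res$records$name, c("r1;size=3", "r3;size=2"))
  expect_equal(res$records$sequence, c("AAAA", "CCCC"))
  expect_equal(res$report$input_records, 5L)
  expect_equal(res$report$unique_records, 2L)

  # size tags on input propagate into the totals
  tagged <- seq_records(c("a;size=10", "b;size=5"), c("GGGG", "GGGG"))
  res <- dereplicate(tagged)
  expect_equal(res$records$name, "a;size=15")

  # per-file counts
  two <- list("f1.fa" = seq_records("x", "TTTT"),
              "f2.fa" = seq_records("y", "TTTT"))
  res <- dereplicate(two)
  expect_equal(res$records$name, "x;size=2")
  expect_equal(res$report$entries$files[[1]],
               list("f1.fa" = 1L, "f2.fa" = 1L))
})

test_that("derep conserves multiplicity, is idempotent, and propagates", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    templates <- unique(vapply(1:n, function(i) random_acgt(12),
                               character(1)))
    copies <- sample(1:6, length(templates), replace = TRUE)
    recs <- seq_records(
      paste0("t", seq_len(sum(copies))),
      rep(templates, copies)[sample(sum(copies))]
    )
    res <- dereplicate(recs)
    sizes <- as.integer(sub(".*;size=", "", res$records$name))
    expect_equal(sum(sizes), sum(copies))  # conservation
    expect_equal(sizes, copies[match(res$records$sequence, templates)])

    # idempotence: derep of the derep output changes nothing
    again <- dereplicate(res$records)
    expect_equal(again$records$sequence, res$records$sequence)
    expect_equal(again$records$name, res$records$name)

    # two-step equals one-step as a (sequence, size) multiset
    half <- sample(nrow(recs), nrow(recs) %/% 2)
    a <- recs[half, , drop = FALSE]
    b <- recs[-half, , drop = FALSE]
    da <- dereplicate(structure(a, class = c("seq_tbl", "data.frame")))
    db <- dereplicate(structure(b, class = c("seq_tbl", "data.frame")))
    two_step <- dereplicate(rbind(da$records, db$records))
    one_step <- dereplicate(recs)
    key <- function(d) {
      o <- order(d$records$sequence)
      paste(d$records$sequence[o],
            sub(".*;size=", "", d$records$name[o]))
    }
    expect_equal(key(two_step), key(one_step))
  }
})

test_that("min_size filters output but the report still counts everything", {
  recs <- seq_records(paste0("r", 1:4), c("AA", "AA", "CC", "GG"))
  res <- dereplicate(recs, min_size = 2)
  expect_equal(res$records$name, "r1;size=2")
  expect_equal(res$report$unique_records, 3L)
  expect_equal(res$report$input_records, 4L)
})

test_that("case folding is on by default and can be disabled", {
  recs <- seq_records(c("a", "b"), c("acgt", "ACGT"))
  expect_equal(nrow(dereplicate(recs)$records), 1L)
  expect_equal(nrow(dereplicate(recs, case_sensitive = TRUE)$records), 2L)
})

test_that("the JSON report round-trips", {
  two <- list("f1.fa" = seq_records(c("x", "z"), c("TTTT", "AA")),
              "f2.fa" = seq_records("y;size=3", "TTTT"))
  rep0 <- dereplicate(two)$report
  json <- derep_report_json(rep0)
  back <- derep_report_from_json(json)
  expect_equal(back$input_records, rep0$input_records)
  expect_equal(back$unique_records, rep0$unique_records)
  expect_equal(back$entries$name, rep0$entries$name)
  expect_equal(back$entries$size, rep0$entries$size)
  expect_equal(back$entries$files, rep0$entries$files)
  # file output path
  path <- withr::local_tempfile(fileext = ".json")
  derep_report_json(rep0, path)
  expect_equal(derep_report_from_json(path)$entries$size,
               rep0$entries$size)
})
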