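test_that("length statistics match hand-worked values", {
  s <- length_stats(c(5, 4, 3, 2, 1))
  expect_equal(s$total_bp, 15)
  expect_equal(s$n50, 4)
  expect_equal(s$aun, 55 / 15)
  one <- length_stats(10)
  expect_equal(one$n50, 10)
  expect_equal(one$aun, 10)
  expect_equal(one$mean_len, 10)
  eq <- length_stats(c(7, 7, 7, 7))
  expect_equal(eq$n50, 7)
  expect_equal(eq$aun, 7)
  expect_error(length_stats(numeric(0)), "no sequences")
})

test_that("N50 and auN agree with the brute-force oracle on random multisets", {
  set.seed(31)
  for (i in 1:100) {
    lens <- sample(1:1e5, sample(1:1000, 1), replace = TRUE)
    s <- length_stats(lens)
    expect_equal(s$n50, n50_oracle(lens))
    expect_equal(s$aun, aun_oracle(lens), tolerance = 1e-9)
    expect_true(s$aun >= s$mean_len - 1e-9)
    expect_true(s$aun <= s$max_len)
    expect_true(s$n50 %in% lens)
  }
})

test_that("Nx is non-increasing in x", {
  set.seed(32)
  for (i in 1:20) {
    lens <- sample(1:5000, 200, replace = TRUE)
    nx <- vapply(c(10, 25, 50, 75, 90), function(x) nx_length(lens, x),
                 numeric(1))
    expect_true(all(diff(nx) <= 0))
  }
})

test_that("count_paired folds mates and flags count mismatches", {
  dir <- withr::local_tempdir()
  sim <- sim_records(100, read_length = 50, paired = TRUE, seed = 33)
  r1 <- file.path(dir, "s_R1.fastq"); r2 <- file.path(dir, "s_R2.fastq")
  write_seqs(sim$r1, r1); write_seqs(sim$r2, r2)
  res <- count_paired(c(r1, r2))
  expect_equal(nrow(res), 1L)
  expect_equal(res$count, 100L)
  expect_equal(res$status, "OK")
  expect_equal(res$mate_path, r2)

  # drop one read from R2 -> mismatch
  write_seqs(seq_head(sim$r2, 99), r2)
  res <- count_paired(c(r1, r2))
  expect_equal(nrow(res), 1L)
  expect_equal(res$status, "PAIR_MISMATCH")

  # unpaired file: one entry, no mate
  single <- file.path(dir, "plain.fastq")
  write_seqs(sim_records(7, read_length = 30, seed = 34), single)
  res <- count_paired(single)
  expect_equal(res$count, 7L)
  expect_true(is.na(res$mate_path))
})

test_that("quality encoding inference recovers the generating offset", {
  r33 <- sim_records(200, read_length = 60, phred_offset = 33, seed = 35)
  r64 <- sim_records(200, read_length = 60, phred_offset = 64, seed = 35)
  for (lim in c(1L, 10L, 1000L)) {
    expect_equal(infer_quality_encoding(r33, lim)$offset, 33L)
    expect_equal(infer_quality_encoding(r64, lim)$offset, 64L)
  }
  expect_match(infer_quality_encoding(r33)$encoding_label, "1.8")
  # '!' (ASCII 33) can only be Phred+33
  low <- seq_records("a", "ACGT", quality = "!III")
  expect_equal(infer_quality_encoding(low)$offset, 33L)
  # ASCII 59..63 window is ambiguous
  amb <- seq_records("a", "ACGT", quality = ";<=>")
  expect_equal(infer_quality_encoding(amb)$encoding_label, "undetermined")
  expect_true(is.na(infer_quality_encoding(amb)$offset))
  fasta <- seq_records("a", "ACGT")
  expect_error(infer_quality_encoding(fasta), "qualit")
})

test_that("quality profile averages by position over contributing reads", {
  recs <- seq_records(c("a", "b"), c("AC", "AC"),
                      quality = c("II", "??"))
  prof <- quality_profile(recs, offset = 33)
  expect_equal(prof$per_position_mean_q, c(35, 35))  # Q40 and Q30
  expect_equal(prof$per_position_depth, c(2L, 2L))

  zero <- quality_profile(seq_records("a", "A", quality = "!"), offset = 33)
  expect_equal(zero$per_position_mean_q, 0)

  varlen <- seq_records(c("a", "b"), c("AC", "ACGT"),
                        quality = c("II", "IIII"))
  prof <- quality_profile(varlen, offset = 33)
  expect_equal(length(prof$per_position_mean_q), 4L)
  expect_equal(prof$per_position_depth, c(2L, 2L, 1L, 1L))
  expect_error(quality_profile(varlen, offset = 50), "offset")
})

test_that("stats formatting produces the three output dialects", {
  st <- list(
    "a.fq" = length_stats(c(10, 20, 30)),
    "b.fq" = length_stats(c(5, 5)),
    "c.fq" = length_stats(100)
  )
  raw <- format_stats(st, "raw")
  lines <- strsplit(raw, "\n")[[1]]
  expect_equal(length(lines), 4L)
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == 8L))
  expect_equal(fields[[1]][1:2], c("File", "#Seq"))

  mq <- format_stats(st, "multiqc")
  mq_lines <- strsplit(mq, "\n")[[1]]
  expect_true(startsWith(mq_lines[1], "#"))
  body <- mq_lines[!startsWith(mq_lines, "#")]
  expect_equal(body, lines)

  pretty <- format_stats(st, "pretty")
  expect_equal(length(strsplit(pretty, "\n")[[1]]), 4L)
  expect_error(format_stats(st, "html"), "arg")
})
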