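test_that("duplicate keys fold case, ignore headers/qualities, and separate mates", {
  expect_identical(dedup_key_single(c("acgT", "ACGT")),
                   c("ACGT", "ACGT"))
  expect_false(dedup_key_single("ACGT") == dedup_key_single("ACGA"))
  expect_error(dedup_key_single(""), "non-empty")
  # separator prevents concatenation collisions
  expect_false(dedup_key_paired("AC", "GT") == dedup_key_paired("ACG", "T"))
  # mate order matters
  expect_false(dedup_key_paired("AC", "GT") == dedup_key_paired("GT", "AC"))
  expect_identical(dedup_key_paired("ac", "gt"), dedup_key_paired("AC", "GT"))
  expect_error(dedup_key_paired("AC", c("GT", "AA")), "equal length")
})

test_that("smallest duplicate case: [S1, S1, S2] keeps first occurrences in order", {
  for (mode in c("exact", "cuckoo")) {
    fq <- write_tmp_fastq(c("ACGTACGT", "ACGTACGT", "TTGACCAA"))
    out <- tempfile(fileext = ".fastq")
    rep <- dedup_fastq(fq, out, mode = mode)
    expect_equal(rep$total_reads, 3)
    expect_equal(rep$kept_reads, 2)
    expect_equal(rep$removed_reads, 1)
    expect_equal(rep$removed_pct, 100 / 3)
    expect_identical(read_fastq(out)$sequence, c("ACGTACGT", "TTGACCAA"))
  }
})

test_that("all-distinct input passes through byte-identically", {
  seqs <- unique(random_seqs(300, len = 25, seed = 6))
  fq <- write_tmp_fastq(seqs)
  out <- tempfile(fileext = ".fastq")
  rep <- dedup_fastq(fq, out, mode = "cuckoo")
  expect_equal(rep$removed_reads, 0)
  expect_identical(readLines(out), readLines(fq))
})

test_that("empty input yields an empty output and zeroed report", {
  fq <- write_tmp_fastq(character(0))
  out <- tempfile(fileext = ".fastq")
  rep <- dedup_fastq(fq, out, mode = "exact")
  expect_equal(rep$total_reads, 0)
  expect_equal(rep$removed_pct, 0)
  expect_equal(nrow(read_fastq(out)), 0L)
})

test_that("exact mode agrees with the duplicated() oracle on randomized inputs", {
  for (seed in 1:5) {
    seqs <- random_seqs(400, len = 8, seed = seed)  # short: many collisions
    fq <- write_tmp_fastq(seqs)
    out <- tempfile(fileext = ".fastq")
    rep <- dedup_fastq(fq, out, mode = "exact", chunk_size = 64L)
    keep_oracle <- !duplicated(toupper(seqs))
    expect_equal(rep$kept_reads, sum(keep_oracle))
    expect_identical(read_fastq(out)$sequence, seqs[keep_oracle])
  }
})

test_that("cuckoo mode never misses a duplicate and loses at most FP-rate uniques", {
  seqs <- random_seqs(2000, len = 10, seed = 8)
  fq <- write_tmp_fastq(seqs)
  out_e <- tempfile(fileext = ".fastq"); out_c <- tempfile(fileext = ".fastq")
  rep_e <- dedup_fastq(fq, out_e, mode = "exact")
  rep_c <- dedup_fastq(fq, out_c, mode = "cuckoo", fingerprint_bits = 16)
  # no false negatives: cuckoo removes at least what exact removes
  expect_gte(rep_c$removed_reads, rep_e$removed_reads)
  # kept set is a subset of the exact kept set (only FP discards differ)
  kept_c <- read_fastq(out_c)$sequence
  kept_e <- read_fastq(out_e)$sequence
  expect_true(all(kept_c %in% kept_e))
  # no two output reads share a key, in either mode
  expect_false(any(duplicated(kept_c)))
  expect_false(any(duplicated(kept_e)))
  # at f=16 over ~2000 distinct-key queries, extra removals are almost
  # surely zero; allow the 99.9% binomial bound at rate 2b/2^f
  bound <- qbinom(0.999, rep_e$kept_reads, 2 * 4 / 2^16)
  expect_lte(rep_c$removed_reads - rep_e$removed_reads, bound)
})

test_that("paired dedup is atomic and keyed jointly", {
  s1 <- c("ACGT", "ACGT", "ACGT", "GGGG")
  s2 <- c("TTTT", "TTTT", "CCCC", "AAAA")
  p1 <- write_tmp_fastq(s1); p2 <- write_tmp_fastq(s2)
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  rep <- dedup_fastq(p1, o1, p2, o2, mode = "exact")
  # only the (ACGT,TTTT) pair repeats; a discarded pair counts 2 reads
  expect_equal(rep$total_reads, 8)
  expect_equal(rep$removed_reads, 2)
  r1 <- read_fastq(o1); r2 <- read_fastq(o2)
  expect_equal(nrow(r1), nrow(r2))
  expect_identical(r1$sequence, c("ACGT", "ACGT", "GGGG"))
  expect_identical(r2$sequence, c("TTTT", "CCCC", "AAAA"))
})

test_that("paired dedup enforces the orphan policy mid-stream", {
  p1 <- write_tmp_fastq(random_seqs(3, seed = 1))
  p2 <- write_tmp_fastq(random_seqs(5, seed = 2))
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  expect_error(dedup_fastq(p1, o1, p2, o2), "3 vs 5",
               class = "fastq_pairing_error")
  expect_message(
    rep <- dedup_fastq(p1, o1, p2, o2, orphan_policy = "drop_tail"),
    "orphan")
  expect_equal(rep$total_reads, 6)
  expect_error(dedup_fastq(p1, o1, p2), "out2")
})

test_that("a full filter chains transparently and results stay correct", {
  seqs <- rep(random_seqs(500, len = 12, seed = 10), each = 2)  # every read duplicated
  fq <- write_tmp_fastq(seqs)
  out <- tempfile(fileext = ".fastq")
  # deliberately undersized first filter: 16 buckets x 4 slots = 64 keys
  rep <- dedup_fastq(fq, out, mode = "cuckoo", num_buckets = 16,
                     max_kicks = 50, chunk_size = 128L)
  expect_gt(rep$filters_chained, 1)
  kept <- read_fastq(out)$sequence
  expect_false(any(duplicated(kept)))
  # chained-mode kept set is a subset of the exact kept set
  out_e <- tempfile(fileext = ".fastq")
  rep_e <- dedup_fastq(fq, out_e, mode = "exact")
  expect_true(all(kept %in% read_fastq(out_e)$sequence))
  expect_gte(rep$removed_reads, rep_e$removed_reads)
})

test_that("dedup reports round-trip through the JSON report file", {
  fq <- write_tmp_fastq(c("ACGT", "ACGT", "TTGA"))
  out <- tempfile(fileext = ".fastq")
  rpt <- tempfile(fileext = ".json")
  dedup_fastq(fq, out, mode = "exact", report = rpt)
  doc <- jsonlite::read_json(rpt)
  expect_equal(doc$result$total_reads, 3)
  expect_equal(doc$result$removed_reads, 1)
  expect_equal(doc$tool, "dedupcf")
})
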