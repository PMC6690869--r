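test_that("parameter validation names the offending field", {
  expect_error(cuckoo_filter(fingerprint_bits = 3), "fingerprint_bits")
  expect_error(cuckoo_filter(fingerprint_bits = 33), "fingerprint_bits")
  expect_error(cuckoo_filter(bucket_slots = 0), "bucket_slots")
  expect_error(cuckoo_filter(max_kicks = 0), "max_kicks")
  expect_error(cuckoo_filter(num_buckets = 100), "num_buckets")
  expect_error(cuckoo_filter(expected_items = -1), "expected_items")
  expect_error(fingerprint_of("ACGT", fingerprint_bits = 2),
               "fingerprint_bits")
  expect_error(fingerprint_of(""), "non-empty")
})

test_that("table sizing targets a 90% design load on a power-of-two grid", {
  cf0 <- cuckoo_filter(0)
  expect_equal(cf_item_count(cf0), 0)
  expect_equal(cf_load_factor(cf0), 0)
  # 1000/0.90 = 1111.1; 4*256 = 1024 < 1112 <= 2048 = 4*512
  cf <- cuckoo_filter(1000, bucket_slots = 4)
  expect_equal(cf$num_buckets, 512)
  expect_equal(sizing_num_buckets(0, 4), 1)
})

test_that("fingerprints are deterministic, in range, and match frozen reference values", {
  x <- random_seqs(200, len = 25, seed = 11)
  expect_identical(fingerprint_of(x, 8), fingerprint_of(x, 8))
  fp8 <- fingerprint_of(x, 8)
  expect_true(all(fp8 >= 1 & fp8 <= 255))
  fp16 <- fingerprint_of(x, 16)
  expect_true(all(fp16 >= 1 & fp16 <= 65535))
  # frozen values computed once with an independent reference
  # implementation of the same seeded FNV-1a/avalanche hash
  expect_equal(fingerprint_of("ACGT", 8, seed = 0), 104)
  expect_equal(fingerprint_of("ACGT", 16, seed = 0), 65128)
  expect_equal(fingerprint_of("ACGT", 32, seed = 0), 4051041896)
  expect_equal(fingerprint_of("ACGT", 16, seed = 42), 49700)
  expect_equal(fingerprint_of("TTAGGC", 16, seed = 42), 61504)
  expect_equal(fingerprint_of("ACGT", 8, seed = 42), 36)
})

test_that("candidate buckets use the XOR involution and match frozen indices", {
  items <- random_seqs(10000, len = 20, seed = 5)
  cb <- candidate_buckets(items, num_buckets = 1024, seed = 42)
  expect_true(all(cb$i1 >= 0 & cb$i1 < 1024))
  expect_true(all(cb$i2 >= 0 & cb$i2 < 1024))
  # alt(alt(i1)) == i1: recompute the alternate from i2
  back <- .cf_alt_index(cb$i2, cb$fingerprint, 1024, 16, 42)
  expect_equal(back, cb$i1)
  # frozen first-index values from the independent hash reference
  one <- candidate_buckets(c("ACGT", "TTAGGC"), 1024, seed = 42)
  expect_equal(one$i1, c(990, 18))
  expect_equal(one$i2[1], 306)
  # degenerate single-bucket table
  d <- candidate_buckets(items[1:5], num_buckets = 1)
  expect_true(all(d$i1 == 0 & d$i2 == 0))
})

test_that("first bucket index is approximately uniform (chi-square, alpha = 0.001)", {
  items <- random_seqs(10000, len = 20, seed = 9)
  cb <- candidate_buckets(items, num_buckets = 1024, seed = 42)
  observed <- tabulate(cb$i1 + 1, nbins = 1024)
  p <- stats::chisq.test(observed)$p.value
  expect_gt(p, 0.001)
})

test_that("insert/contains/delete honour set semantics and multiset storage", {
  cf <- cuckoo_filter(100)
  expect_false(cf_contains(cf, "ACGT"))
  expect_true(cf_insert(cf, "ACGT"))
  expect_true(cf_contains(cf, "ACGT"))
  expect_equal(cf_item_count(cf), 1)
  # singleton round trip
  expect_true(cf_delete(cf, "ACGT"))
  expect_false(cf_contains(cf, "ACGT"))
  expect_false(cf_delete(cf, "ACGT"))  # now empty
  # multiset: two inserts survive one delete
  cf_insert(cf, c("ACGT", "ACGT"))
  expect_equal(cf_item_count(cf), 2)
  expect_true(cf_delete(cf, "ACGT"))
  expect_true(cf_contains(cf, "ACGT"))
  # load factor bookkeeping: one item in a 1x4 table
  cf1 <- cuckoo_filter(num_buckets = 1, bucket_slots = 4)
  cf_insert(cf1, "TTTT")
  expect_equal(cf_load_factor(cf1), 0.25)
})

test_that("no false negatives over many inserts and item_count is conserved", {
  cf <- cuckoo_filter(20000)
  keys <- indexed_keys(20000)
  ok <- cf_insert(cf, keys)
  expect_true(all(ok))
  expect_true(all(cf_contains(cf, keys)))
  expect_equal(cf_item_count(cf), 20000)
  n_del <- 500
  expect_true(all(cf_delete(cf, keys[1:n_del])))
  expect_equal(cf_item_count(cf), 20000 - n_del)
})

test_that("failed inserts roll back: counts conserved, no resident key lost", {
  # tiny table fills quickly, forcing many failed inserts with evictions
  cf <- cuckoo_filter(num_buckets = 8, bucket_slots = 4, max_kicks = 50,
                      fingerprint_bits = 16)
  keys <- indexed_keys(200, "fill")
  res <- cf_insert(cf, keys)
  expect_true(any(!res))  # must eventually fill
  # item_count == successful inserts, despite interleaved failures
  expect_equal(cf_item_count(cf), sum(res))
  # a failed insert's rollback must not evict any resident fingerprint:
  # every successfully inserted key is still a member
  expect_true(all(cf_contains(cf, keys[res])))
})

test_that("achieved load before first failure reaches 90% for most seeds", {
  m <- 256; b <- 4
  loads <- vapply(0:19, function(sd) {
    cf <- cuckoo_filter(num_buckets = m, bucket_slots = b,
                        fingerprint_bits = 16, seed = sd)
    res <- cf_insert(cf, indexed_keys(m * b + 64, paste0("s", sd, "_")))
    (which(!res)[1] - 1) / (m * b)
  }, numeric(1))
  expect_gte(sum(loads >= 0.90), 18)
})

test_that("empirical false-positive rate stays within 1.5x the analytic bound", {
  # bound: 2*b/2^f, measured at ~90% load over never-inserted probes
  for (f in c(8, 12, 16)) {
    b <- 4; m <- 1024
    cf <- cuckoo_filter(num_buckets = m, bucket_slots = b,
                        fingerprint_bits = f, seed = 1)
    n_load <- floor(0.9 * m * b)
    cf_insert(cf, indexed_keys(n_load, "in"))
    n_probe <- if (f == 16) 3e5 else 1e5
    fp_rate <- mean(cf_contains(cf, indexed_keys(n_probe, "out")))
    expect_lte(fp_rate, 1.5 * 2 * b / 2^f)
  }
})
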