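#' Create a partial-key cuckoo filter
#'
#' A cuckoo filter is a compact approximate-membership structure: instead of
#' whole items it stores short fingerprints in a table of `m` buckets with
#' `b` slots each, and every item has exactly two candidate buckets. Lookups
#' can return false positives (two items sharing a fingerprint and a bucket)
#' at a rate of about `2 * b / 2^f`, but never false negatives for items
#' that were inserted and not deleted — the property that makes the filter
#' safe for duplicate-read detection, where a false negative would leave a
#' duplicate in the output.
#'
#' The table is sized as the smallest power of two `m` such that `m * b`
#' slots can hold `expected_items` at a design load of 90%. A power-of-two
#' bucket count is required so that the alternate bucket can be computed by
#' XOR (`i2 = i1 XOR hash(fingerprint)`), which makes the mapping an
#' involution: either bucket can recover the other from the stored
#' fingerprint alone.
#'
#' @param expected_items Number of distinct items the filter should hold at
#'   no more than 90% table load.
#' @param fingerprint_bits Bits per fingerprint (`f`), between 4 and 32.
#'   Default 16, giving a false-positive rate of about `2*4/2^16 = 1.2e-4`
#'   with the default 4-slot buckets — small enough that accidentally
#'   discarding a unique read is negligible at typical dataset sizes.
#' @param bucket_slots Slots per bucket (`b`), default 4.
#' @param num_buckets Optional explicit bucket count (must be a power of
#'   two); overrides the sizing rule.
#' @param max_kicks Maximum fingerprint relocations before an insert is
#'   declared to have failed (filter full). Default 500.
#' @param seed Integer seed driving hashing and the eviction random walk;
#'   fixed seed gives byte-reproducible behaviour. Default 42.
#'
#' @return An object of class `cuckoo_filter`.
#'
#' @examples
#' cf <- cuckoo_filter(1000)
#' cf_insert(cf, "ACGT")
#' cf_contains(cf, c("ACGT", "TTTT"))
#' @export
cuckoo_filter <- function(expected_items = 2^20, fingerprint_bits = 16L,
                          bucket_slots = 4L, num_buckets = NULL,
                          max_kicks = 500L, seed = 42) {
  f <- as.integer(fingerprint_bits)
  b <- as.integer(bucket_slots)
  mk <- as.integer(max_kicks)
  if (is.na(f) || f < 4L || f > 32L)
    stop("fingerprint_bits must be an integer in [4, 32]", call. = FALSE)
  if (is.na(b) || b < 1L)
    stop("bucket_slots must be a positive integer", call. = FALSE)
  if (is.na(mk) || mk < 1L)
    stop("max_kicks must be a positive integer", call. = FALSE)
  if (!is.numeric(expected_items) || length(expected_items) != 1L ||
      is.na(expected_items) || expected_items < 0)
    stop("expected_items must be a single non-negative number", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  if (is.null(num_buckets)) {
    m <- sizing_num_buckets(expected_items, b)
  } else {
    m <- as.numeric(num_buckets)
    if (is.na(m) || m < 1 || bitwAnd_pow2_check(m))
      stop("num_buckets must be a power of two >= 1", call. = FALSE)
  }
  obj <- list(ptr = .cf_new(f, b, m, mk, seed),
              fingerprint_bits = f, bucket_slots = b, num_buckets = m,
              max_kicks = mk, seed = seed)
  class(obj) <- "cuckoo_filter"
  obj
}

# smallest power of two m with m*b >= expected/0.90 (design load <= 90%)
sizing_num_buckets <- function(expected_items, b) {
  need <- expected_items / 0.90
  m <- 1
  while (m * b < need) m <- m * 2
  m
}

# TRUE when m is NOT a power of two (doubles are exact for m < 2^53)
bitwAnd_pow2_check <- function(m) {
  if (m != round(m)) return(TRUE)
  p <- 1
  while (p < m) p <- p * 2
  p != m
}

#' Insert items into a cuckoo filter
#'
#' Each item's fingerprint is placed in one of its two candidate buckets; if
#' both are full, resident fingerprints are kicked to their alternate
#' buckets (a random walk of at most `max_kicks` relocations). A failed
#' insert reports `FALSE` — the filter is full — and leaves the table
#' holding exactly its prior contents, so callers can chain a fresh filter.
#' Inserting the same item twice stores two fingerprint copies (multiset
#' semantics).
#'
#' @param filter A `cuckoo_filter`.
#' @param items Character vector of non-empty keys.
#' @return Logical vector: `TRUE` where the insert succeeded.
#' @export
cf_insert <- function(filter, items) {
  stopifnot(inherits(filter, "cuckoo_filter"))
  .cf_insert(filter$ptr, as.character(items))
}

#' Query cuckoo-filter membership
#'
#' Returns `TRUE` when the item's fingerprint is found in either of its
#' candidate buckets. Never `FALSE` for an item that was successfully
#' inserted and not deleted; may be `TRUE` for a never-inserted item with
#' probability about `2 * bucket_slots / 2^fingerprint_bits`.
#'
#' @inheritParams cf_insert
#' @return Logical vector of membership flags.
#' @export
cf_contains <- function(filter, items) {
  stopifnot(inherits(filter, "cuckoo_filter"))
  .cf_contains(filter$ptr, as.character(items))
}

#' Delete items from a cuckoo filter
#'
#' Removes one matching fingerprint from a candidate bucket per item, if
#' present. Deleting an item that was never inserted is hazardous: it may
#' remove the fingerprint of a different, colliding item, after which that
#' item would turn into a false negative. Only delete items known to have
#' been inserted.
#'
#' @inheritParams cf_insert
#' @return Logical vector: `TRUE` where a fingerprint was removed.
#' @export
cf_delete <- function(filter, items) {
  stopifnot(inherits(filter, "cuckoo_filter"))
  .cf_delete(filter$ptr, as.character(items))
}

#' Number of stored fingerprints
#' @param filter A `cuckoo_filter`.
#' @return Count of occupied slots.
#' @export
cf_item_count <- function(filter) {
  stopifnot(inherits(filter, "cuckoo_filter"))
  .cf_info(filter$ptr)$item_count
}

#' Fraction of occupied slots
#' @param filter A `cuckoo_filter`.
#' @return `item_count / (num_buckets * bucket_slots)`, in `[0, 1]`.
#' @export
cf_load_factor <- function(filter) {
  stopifnot(inherits(filter, "cuckoo_filter"))
  info <- .cf_info(filter$ptr)
  info$item_count / (info$num_buckets * info$bucket_slots)
}

#' Derive an item's fingerprint
#'
#' The fingerprint is the low `fingerprint_bits` bits of a seeded 64-bit
#' hash of the item, remapped to 1 when the masked value is 0 (0 marks an
#' empty slot). Deterministic for fixed item, width and seed.
#'
#' @param items Character vector of non-empty keys.
#' @param fingerprint_bits Fingerprint width in bits (4–32).
#' @param seed Hash seed.
#' @return Numeric vector of fingerprint values in `[1, 2^f - 1]`.
#' @export
fingerprint_of <- function(items, fingerprint_bits = 16L, seed = 42) {
  f <- as.integer(fingerprint_bits)
  if (is.na(f) || f < 4L || f > 32L)
    stop("fingerprint_bits must be an integer in [4, 32]", call. = FALSE)
  .cf_fingerprint(as.character(items), f, seed)
}

#' Candidate buckets of an item
#'
#' The first index is `hash(item) mod m`; the alternate is obtained by
#' XORing with a hash of the fingerprint, so the mapping is an involution:
#' applying it from `i2` with the same fingerprint returns `i1`. Requires a
#' power-of-two bucket count.
#'
#' @param items Character vector of non-empty keys.
#' @param num_buckets Bucket count `m` (power of two).
#' @param fingerprint_bits Fingerprint width in bits.
#' @param seed Hash seed.
#' @return Data frame with columns `i1`, `i2` (0-based bucket indices) and
#'   `fingerprint`.
#' @export
candidate_buckets <- function(items, num_buckets, fingerprint_bits = 16L,
                              seed = 42) {
  m <- as.numeric(num_buckets)
  if (is.na(m) || m < 1 || bitwAnd_pow2_check(m))
    stop("num_buckets must be a power of two >= 1", call. = FALSE)
  res <- .cf_buckets(as.character(items), m, as.integer(fingerprint_bits),
                     seed)
  data.frame(i1 = res$i1, i2 = res$i2, fingerprint = res$fingerprint)
}

#' @export
print.cuckoo_filter <- function(x, ...) {
  info <- .cf_info(x$ptr)
  cap <- info$num_buckets * info$bucket_slots
  cat(sprintf(
    "cuckoo filter: %g buckets x %d slots (f = %d bits, max_kicks = %d, seed = %g)\n",
    info$num_buckets, info$bucket_slots, info$fingerprint_bits,
    info$max_kicks, info$seed))
  cat(sprintf("  items: %g / %g slots (load %.3f)\n", info$item_count, cap,
              info$item_count / cap))
  invisible(x)
}
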