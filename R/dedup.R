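#' Duplicate key of single-end reads
#'
#' Two reads are duplicates when their sequences are exactly identical;
#' headers and quality strings never participate. The key is the
#' uppercase-normalised sequence, so case differences do not split
#' duplicates. Reverse complements and `N`-containing reads are treated
#' literally: no strand canonicalisation is applied.
#'
#' @param sequences Character vector of read sequences.
#' @return Character vector of keys.
#' @export
dedup_key_single <- function(sequences) {
  if (any(!nzchar(sequences)))
    stop("sequences must be non-empty", call. = FALSE)
  toupper(sequences)
}

#' Duplicate key of read pairs
#'
#' The pair key is `uppercase(seq1) <SEP> uppercase(seq2)` where `<SEP>` is
#' the unit-separator byte `0x1F`, which cannot occur in sequence text; the
#' separator prevents concatenation collisions such as `("AC","GT")` vs
#' `("ACG","T")`. The key is order-sensitive: mate-swapped pairs are not
#' duplicates.
#'
#' @param seq1,seq2 Character vectors of mate-1 and mate-2 sequences.
#' @return Character vector of pair keys.
#' @export
dedup_key_paired <- function(seq1, seq2) {
  if (length(seq1) != length(seq2))
    stop("mate sequence vectors must have equal length", call. = FALSE)
  if (any(!nzchar(seq1)) || any(!nzchar(seq2)))
    stop("sequences must be non-empty", call. = FALSE)
  paste0(toupper(seq1), "\x1F", toupper(seq2))
}

# Membership backends share one interface: $check_insert(keys) returns a
# logical keep-vector (TRUE = first occurrence, kept), and $n_filters().

backend_exact <- function() {
  ptr <- .exact_new()
  list(check_insert = function(keys) .exact_check_insert(ptr, keys),
       n_filters = function() 0L,
       distinct = function() .exact_size(ptr))
}

# Chain of cuckoo filters: all filters are consulted for membership, new
# keys go into the newest. When an insert fails (filter full) a fresh
# filter with the same geometry is appended and processing resumes; the
# no-false-negative contract survives because earlier filters keep their
# fingerprints. Growing a single filter in place is impossible: the
# fingerprints cannot be rehashed without the original keys.
backend_cuckoo <- function(fingerprint_bits, bucket_slots, num_buckets,
                           max_kicks, seed) {
  filters <- list(.cf_new(fingerprint_bits, bucket_slots, num_buckets,
                          max_kicks, seed))
  check_insert <- function(keys) {
    n <- length(keys)
    keep <- logical(n)
    done <- 0L
    while (done < n) {
      res <- .cf_check_insert_chain(filters, keys[(done + 1L):n])
      p <- as.integer(res$processed)
      if (p > 0L) keep[(done + 1L):(done + p)] <- res$keep[seq_len(p)]
      done <- done + p
      if (done < n) {
        # filter full mid-chunk: chain a new one and resume
        filters[[length(filters) + 1L]] <<-
          .cf_new(fingerprint_bits, bucket_slots, num_buckets, max_kicks,
                  seed + length(filters))
      }
    }
    keep
  }
  list(check_insert = check_insert,
       n_filters = function() length(filters))
}

#' Remove exact duplicate reads from FASTQ files
#'
#' Streams one FASTQ file (single-end) or two synchronized files
#' (paired-end), keeps the first occurrence of every duplicate key and
#' discards the rest, preserving input order. A duplicate is an exact,
#' order-sensitive, full-sequence match (pairs are keyed jointly; see
#' [dedup_key_paired()]); headers and qualities are ignored.
#'
#' Two membership backends are available. `"cuckoo"` uses a chain of
#' cuckoo filters (see [cuckoo_filter()]): memory stays compact and no
#' duplicate is ever missed, but a false positive may very rarely discard a
#' unique read (probability about `2 * bucket_slots / 2^fingerprint_bits`
#' per distinct read; about 1.2e-4 at the defaults). `"exact"` keeps a
#' hash set of full keys: zero error in both directions at the cost of
#' memory proportional to the number of distinct reads.
#'
#' When no `expected_reads` hint is given the first filter is sized for
#' 2^20 keys; on overflow additional filters are chained transparently
#' (reported in the result, never an error).
#'
#' @param in1 Input FASTQ (mate 1 for paired data); plain or gzip.
#' @param out1 Output FASTQ for kept reads (gzip when ending `.gz`).
#' @param in2,out2 Mate-2 input/output for paired-end data (both or
#'   neither).
#' @param mode `"cuckoo"` (default) or `"exact"`.
#' @param expected_reads Optional hint used to size the first filter.
#' @param fingerprint_bits,bucket_slots,max_kicks,seed Filter parameters,
#'   see [cuckoo_filter()].
#' @param num_buckets Optional explicit bucket count (power of two).
#' @param orphan_policy Pairing policy for unequal files, see
#'   [read_fastq_paired()].
#' @param chunk_size Records per streaming chunk.
#' @param report Optional path; when given, the report is also written
#'   there as JSON.
#' @return A `dedup_report`: counters `total_reads`, `kept_reads`,
#'   `removed_reads`, `removed_pct`, plus `mode`, `filter_params` and
#'   `filters_chained`. Counters count reads, so a discarded pair adds 2
#'   to `removed_reads`.
#'
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' write_fastq(data.frame(read_id = c("r1", "r2", "r3"),
#'                        sequence = c("ACGT", "ACGT", "TTGA"),
#'                        plus_line = "", quality = c("IIII", "IIII", "IIII")),
#'             fq)
#' out <- tempfile(fileext = ".fastq")
#' dedup_fastq(fq, out)
#' @export
dedup_fastq <- function(in1, out1, in2 = NULL, out2 = NULL,
                        mode = c("cuckoo", "exact"), expected_reads = NULL,
                        fingerprint_bits = 16L, bucket_slots = 4L,
                        num_buckets = NULL, max_kicks = 500L, seed = 42,
                        orphan_policy = c("error", "drop_tail"),
                        chunk_size = 50000L, report = NULL) {
  mode <- match.arg(mode)
  orphan_policy <- match.arg(orphan_policy)
  paired <- !is.null(in2)
  if (paired && is.null(out2))
    stop("paired input requires both out1 and out2", call. = FALSE)
  if (!paired && !is.null(out2))
    stop("out2 given without in2", call. = FALSE)

  backend <- if (mode == "exact") {
    backend_exact()
  } else {
    f <- as.integer(fingerprint_bits)
    b <- as.integer(bucket_slots)
    if (is.na(f) || f < 4L || f > 32L)
      stop("fingerprint_bits must be an integer in [4, 32]", call. = FALSE)
    m <- if (!is.null(num_buckets)) {
      if (bitwAnd_pow2_check(num_buckets))
        stop("num_buckets must be a power of two", call. = FALSE)
      as.numeric(num_buckets)
    } else {
      sizing_num_buckets(if (is.null(expected_reads)) 2^20
                         else as.numeric(expected_reads), b)
    }
    backend_cuckoo(f, b, m, as.integer(max_kicks), seed)
  }

  total <- 0; kept <- 0
  if (paired) {
    rd1 <- fastq_reader(in1, chunk_size); on.exit(rd1$close(), add = TRUE)
    rd2 <- fastq_reader(in2, chunk_size); on.exit(rd2$close(), add = TRUE)
    wr1 <- fastq_writer(out1); on.exit(wr1$close(), add = TRUE)
    wr2 <- fastq_writer(out2); on.exit(wr2$close(), add = TRUE)
    repeat {
      c1 <- rd1$read_chunk()
      c2 <- rd2$read_chunk()
      n1 <- if (is.null(c1)) 0L else nrow(c1)
      n2 <- if (is.null(c2)) 0L else nrow(c2)
      if (n1 == 0L && n2 == 0L) break
      if (n1 != n2) {
        # one file ran short: drain both to report full counts
        drain <- function(rd) repeat if (is.null(rd$read_chunk())) break
        drain(rd1); drain(rd2)
        if (orphan_policy == "error") fastq_pairing_error(rd1$count(),
                                                          rd2$count())
        message(sprintf("dropped %d orphan record(s) from the longer file",
                        abs(rd1$count() - rd2$count())))
        n <- min(n1, n2)
        if (n == 0L) break
        c1 <- c1[seq_len(n), , drop = FALSE]
        c2 <- c2[seq_len(n), , drop = FALSE]
      }
      keys <- dedup_key_paired(c1$sequence, c2$sequence)
      keep <- backend$check_insert(keys)
      total <- total + 2L * length(keys)
      kept <- kept + 2L * sum(keep)
      wr1$write_records(c1[keep, , drop = FALSE])
      wr2$write_records(c2[keep, , drop = FALSE])
    }
  } else {
    rd <- fastq_reader(in1, chunk_size); on.exit(rd$close(), add = TRUE)
    wr <- fastq_writer(out1); on.exit(wr$close(), add = TRUE)
    repeat {
      ch <- rd$read_chunk()
      if (is.null(ch)) break
      keys <- dedup_key_single(ch$sequence)
      keep <- backend$check_insert(keys)
      total <- total + length(keys)
      kept <- kept + sum(keep)
      wr$write_records(ch[keep, , drop = FALSE])
    }
  }

  res <- dedup_report(total, kept, mode,
                      filter_params = if (mode == "cuckoo")
                        list(fingerprint_bits = as.integer(fingerprint_bits),
                             bucket_slots = as.integer(bucket_slots),
                             max_kicks = as.integer(max_kicks),
                             seed = seed) else NULL,
                      filters_chained = backend$n_filters())
  if (!is.null(report)) write_json_report("dedup", res, report, seed = seed)
  res
}

dedup_report <- function(total, kept, mode, filter_params = NULL,
                         filters_chained = 0L) {
  removed <- total - kept
  structure(list(
    total_reads = total, kept_reads = kept, removed_reads = removed,
    removed_pct = if (total == 0) 0 else 100 * removed / total,
    mode = mode, filter_params = filter_params,
    filters_chained = filters_chained),
    class = "dedup_report")
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("duplicate-removal report (%s mode)\n", x$mode))
  cat(sprintf("  total reads:   %d\n", as.integer(x$total_reads)))
  cat(sprintf("  kept reads:    %d\n", as.integer(x$kept_reads)))
  cat(sprintf("  removed reads: %d (%.2f%%)\n", as.integer(x$removed_reads),
              x$removed_pct))
  if (x$mode == "cuckoo")
    cat(sprintf("  filters chained: %d\n", as.integer(x$filters_chained)))
  invisible(x)
}
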