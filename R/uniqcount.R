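#' @title Unique-read counting
#' @description Exact multiset counting of duplicate keys in a dataset:
#'   how many reads (or pairs) there are in total, how many distinct
#'   sequences occur, how many occur exactly once, and how many reads are
#'   redundant copies. After a correct duplicate removal the counts must
#'   satisfy `unique_once == distinct == total` — only redundant reads may
#'   disappear, and the number of distinct reads must be conserved.
#' @name uniqcount
NULL

# multiset counts over a key vector; the keys use the same rule as dedup
count_keys <- function(keys) {
  total <- length(keys)
  dup <- duplicated(keys)
  distinct <- total - sum(dup)
  # keys seen more than once: distinct keys among the duplicated tail
  multi <- sum(!duplicated(keys[dup]))
  structure(list(total = total, distinct = distinct,
                 unique_once = distinct - multi,
                 redundant = total - distinct),
            class = "unique_count_report")
}

#' Count unique reads in a FASTQ dataset
#'
#' Counts the multiset of duplicate keys of a single-end file or a
#' synchronized pair of files (pairs are keyed jointly, with the same key
#' rule as [dedup_fastq()], so counts and dedup reports are directly
#' comparable). `unique_once` counts keys that appear exactly once — the
#' "unique reads" of a dataset; `redundant = total - distinct` is the
#' number of reads a perfect duplicate remover would delete.
#'
#' @param path1 FASTQ path (mate 1 when paired).
#' @param path2 Optional mate-2 path; when given, counting is over pair
#'   keys.
#' @param orphan_policy Pairing policy for unequal files, see
#'   [read_fastq_paired()].
#' @param report Optional path for a JSON copy of the report.
#' @return A `unique_count_report`: `total`, `distinct`, `unique_once`,
#'   `redundant` (unit = read, or pair when `path2` is given).
#' @export
count_unique <- function(path1, path2 = NULL,
                         orphan_policy = c("error", "drop_tail"),
                         report = NULL) {
  orphan_policy <- match.arg(orphan_policy)
  keys <- if (is.null(path2)) {
    dedup_key_single(read_fastq(path1)$sequence)
  } else {
    p <- read_fastq_paired(path1, path2, orphan_policy)
    dedup_key_paired(p$mate1$sequence, p$mate2$sequence)
  }
  res <- count_keys(keys)
  if (!is.null(report)) write_json_report("count-unique", res, report)
  res
}

#' @export
print.unique_count_report <- function(x, ...) {
  cat(sprintf(
    "total %d | distinct %d | appear-once %d | redundant %d\n",
    as.integer(x$total), as.integer(x$distinct),
    as.integer(x$unique_once), as.integer(x$redundant)))
  invisible(x)
}
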