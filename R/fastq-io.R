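#' @title Streaming FASTQ input/output
#' @description Readers and writers for the strict 4-line FASTQ dialect,
#'   plain or gzip-compressed, with positional pairing of synchronized
#'   paired-end files. Records are represented as data frames with columns
#'   `read_id` (header without the leading `@`), `sequence`, `plus_line`
#'   (text after `+`, often empty) and `quality`.
#' @name fastq_io
NULL

fastq_format_error <- function(msg, path = NULL) {
  stop(errorCondition(paste0("FASTQ format error", if (!is.null(path))
    paste0(" in '", path, "'"), ": ", msg),
    class = c("fastq_format_error", "dedupcf_error")))
}

fastq_io_error <- function(msg) {
  stop(errorCondition(msg, class = c("dedupcf_io_error", "dedupcf_error")))
}

fastq_pairing_error <- function(n1, n2) {
  stop(errorCondition(
    sprintf("paired FASTQ files have unequal record counts: %d vs %d", n1, n2),
    class = c("fastq_pairing_error", "dedupcf_error")))
}

# Chunked reader over a (possibly gzipped) 4-line FASTQ file. gzfile()
# autodetects gzip by magic bytes and reads plain text transparently.
# Returns a list of closures: $read_chunk() -> data.frame or NULL at EOF,
# $count() -> records yielded so far, $close().
fastq_reader <- function(path, chunk_size = 50000L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    fastq_io_error(paste0("cannot open FASTQ file: '", path, "'"))
  con <- gzfile(path, open = "rt")
  nrec <- 0L
  read_chunk <- function() {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) return(NULL)
    if (length(lines) %% 4L != 0L)
      fastq_format_error(sprintf(
        "truncated record %d (file ends mid-record)",
        nrec + length(lines) %/% 4L + 1L), path)
    n <- length(lines) %/% 4L
    hdr <- lines[seq(1L, by = 4L, length.out = n)]
    seqs <- lines[seq(2L, by = 4L, length.out = n)]
    plus <- lines[seq(3L, by = 4L, length.out = n)]
    qual <- lines[seq(4L, by = 4L, length.out = n)]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad))
      fastq_format_error(sprintf(
        "record %d: header does not start with '@' (wrapped or corrupt input)",
        nrec + bad[1L]), path)
    bad <- which(!startsWith(plus, "+"))
    if (length(bad))
      fastq_format_error(sprintf(
        "record %d: separator line does not start with '+'",
        nrec + bad[1L]), path)
    bad <- which(nchar(seqs) != nchar(qual) | nchar(seqs) == 0L)
    if (length(bad))
      fastq_format_error(sprintf(
        "record %d: sequence and quality lengths differ (or empty sequence)",
        nrec + bad[1L]), path)
    nrec <<- nrec + n
    data.frame(read_id = substring(hdr, 2L), sequence = seqs,
               plus_line = substring(plus, 2L), quality = qual)
  }
  list(read_chunk = read_chunk,
       count = function() nrec,
       close = function() close(con))
}

#' Read a FASTQ file
#'
#' Reads a strict 4-line FASTQ file (plain or gzip, autodetected) into a
#' data frame. Wrapped (multi-line) records are rejected rather than
#' repaired; truncated files, missing `@`/`+` markers and sequence/quality
#' length mismatches raise a format error naming the offending record.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return Data frame with columns `read_id`, `sequence`, `plus_line`,
#'   `quality`, in file order.
#' @export
read_fastq <- function(path) {
  rd <- fastq_reader(path)
  on.exit(rd$close())
  chunks <- list()
  repeat {
    ch <- rd$read_chunk()
    if (is.null(ch)) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  if (length(chunks) == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      plus_line = character(), quality = character()))
  do.call(rbind, chunks)
}

# Writer closure for canonical 4-line FASTQ; gzip when path ends ".gz".
fastq_writer <- function(path) {
  con <- tryCatch(
    if (endsWith(path, ".gz")) gzfile(path, open = "wt")
    else file(path, open = "wt"),
    error = function(e)
      fastq_io_error(paste0("cannot open output file '", path, "': ",
                            conditionMessage(e))))
  n <- 0L
  list(write_records = function(rec) {
    if (nrow(rec) == 0L) return(invisible(0L))
    lines <- as.vector(rbind(paste0("@", rec$read_id), rec$sequence,
                             paste0("+", rec$plus_line), rec$quality))
    writeLines(lines, con)
    n <<- n + nrow(rec)
  },
  count = function() n,
  close = function() close(con))
}

#' Write records to a FASTQ file
#'
#' Emits canonical 4-line records; output is gzip-compressed when `path`
#' ends in `.gz`. A read/write/read round trip reproduces records exactly.
#'
#' @param records Data frame as produced by [read_fastq()].
#' @param path Output path.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("read_id", "sequence", "plus_line", "quality") %in%
                  names(records)))
  if (any(nchar(records$sequence) != nchar(records$quality)))
    fastq_format_error("sequence and quality lengths differ in records")
  wr <- fastq_writer(path)
  on.exit(wr$close())
  wr$write_records(records)
  invisible(wr$count())
}

#' Read a synchronized pair of FASTQ files
#'
#' Mates are paired positionally: record `k` of the first file with record
#' `k` of the second. No header parsing is attempted. When the files have
#' unequal record counts the `orphan_policy` decides: `"error"` (default)
#' raises a pairing error reporting both counts; `"drop_tail"` keeps the
#' first `min(n1, n2)` pairs and reports the number of orphans dropped via
#' a message.
#'
#' @param path1,path2 Paths to the two mate files.
#' @param orphan_policy `"error"` or `"drop_tail"`.
#' @return List with data frames `mate1` and `mate2` of equal row counts.
#' @export
read_fastq_paired <- function(path1, path2,
                              orphan_policy = c("error", "drop_tail")) {
  orphan_policy <- match.arg(orphan_policy)
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 != n2) {
    if (orphan_policy == "error") fastq_pairing_error(n1, n2)
    n <- min(n1, n2)
    message(sprintf("dropped %d orphan record(s) from the longer file",
                    abs(n1 - n2)))
    r1 <- r1[seq_len(n), , drop = FALSE]
    r2 <- r2[seq_len(n), , drop = FALSE]
  }
  list(mate1 = r1, mate2 = r2)
}
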