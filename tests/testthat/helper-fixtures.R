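# in-code fixtures: FASTQ builders and random key generators

fq_records <- function(sequences, ids = NULL, plus = "", qual_char = "I") {
  n <- length(sequences)
  data.frame(read_id = if (is.null(ids)) sprintf("r%03d", seq_len(n)) else ids,
             sequence = sequences,
             plus_line = rep_len(plus, n),
             quality = strrep(qual_char, nchar(sequences)))
}

write_tmp_fastq <- function(sequences, ..., ext = ".fastq") {
  path <- tempfile(fileext = ext)
  write_fastq(fq_records(sequences, ...), path)
  path
}

# deterministic random DNA sequences / arbitrary string keys
random_seqs <- function(n, len = 30L, seed = 1) {
  withr_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  })
}

# unique string keys (fast, no RNG needed beyond index)
indexed_keys <- function(n, prefix = "key") sprintf("%s%08d", prefix, seq_len(n))

withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# brute-force multiset counter used as the independent oracle for
# count_unique / simulation ground truth
brute_force_counts <- function(keys) {
  tab <- table(keys)
  list(total = length(keys), distinct = length(tab),
       unique_once = sum(tab == 1), redundant = length(keys) - length(tab))
}
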