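#' @title Synthetic read simulator with PCR-duplication ground truth
#' @description Generates FASTQ datasets from a (random or supplied)
#'   reference with a simple per-base substitution error model and a
#'   controlled amplification-duplicate model, and reports the exact
#'   multiset ground truth (distinct / appear-once / redundant reads) of
#'   what was emitted, so duplicate-removal results can be checked against
#'   a known answer.
#' @name simdata
NULL

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
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

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. uniformly from A/C/G/T; the result is
#' deterministic for a fixed seed.
#'
#' @param length Reference length in bases (>= 1).
#' @param seed RNG seed.
#' @return A single character string.
#' @export
simulate_reference <- function(length, seed = 1) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1)
    stop("length must be a positive number", call. = FALSE)
  with_local_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), as.integer(length), replace = TRUE),
          collapse = "")
  })
}

#' Simulation parameters
#'
#' Bundles the knobs of the read simulator. Template count is derived from
#' coverage: `N0 = round(coverage * reference_length / read_length)` for
#' single-end data, halved for paired-end (a fragment contributes two
#' reads). Each template is drawn at a uniform start on the forward
#' strand, substitution errors are applied once per template, and the
#' template is then emitted `1 + extra` times, where `extra` follows the
#' duplication model — so PCR copies are byte-identical to their template,
#' matching the exact-identity duplicate definition of [dedup_fastq()].
#'
#' @param read_length Read length in bases.
#' @param coverage Fold coverage (e.g. 100, 200, 300).
#' @param paired Generate mate pairs?
#' @param insert_size_mean,insert_size_sd Fragment length distribution
#'   (paired only), bases.
#' @param substitution_rate Per-base substitution probability in
#'   `[0, 0.2]`.
#' @param duplication_model `"none"`, `"poisson"` (extra copies ~
#'   Poisson(`dup_rate`)) or `"geometric"` (extra copies ~
#'   Geometric(`dup_rate`), counting failures before the first success).
#' @param dup_rate Poisson mean `lambda >= 0`, or geometric success
#'   probability in `(0, 1]`.
#' @param quality_char Single Phred+33 character used to fill quality
#'   strings (qualities are ignored by deduplication).
#' @param seed RNG seed; identical specs produce byte-identical FASTQ.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(read_length = 100L, coverage = 100, paired = FALSE,
                     insert_size_mean = 300, insert_size_sd = 30,
                     substitution_rate = 0.005,
                     duplication_model = c("none", "poisson", "geometric"),
                     dup_rate = 0, quality_char = "I", seed = 1) {
  duplication_model <- match.arg(duplication_model)
  if (!is.numeric(coverage) || coverage <= 0)
    stop("coverage must be > 0", call. = FALSE)
  if (!is.numeric(substitution_rate) || substitution_rate < 0 ||
      substitution_rate > 0.2)
    stop("substitution_rate must be in [0, 0.2]", call. = FALSE)
  if (duplication_model == "poisson" && dup_rate < 0)
    stop("dup_rate (Poisson lambda) must be >= 0", call. = FALSE)
  if (duplication_model == "geometric" &&
      (dup_rate <= 0 || dup_rate > 1))
    stop("dup_rate (geometric p) must be in (0, 1]", call. = FALSE)
  if (!is.character(quality_char) || nchar(quality_char) != 1L)
    stop("quality_char must be a single character", call. = FALSE)
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 paired = isTRUE(paired),
                 insert_size_mean = insert_size_mean,
                 insert_size_sd = insert_size_sd,
                 substitution_rate = substitution_rate,
                 duplication_model = duplication_model, dup_rate = dup_rate,
                 quality_char = quality_char, seed = seed),
            class = "sim_spec")
}

# apply i.i.d. substitution errors to a character vector of reads;
# vectorised by error round so at most max(errors-per-read) passes run
apply_substitutions <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  L <- nchar(reads)
  nerr <- stats::rbinom(length(reads), L, rate)
  hit <- which(nerr > 0L)
  if (length(hit) == 0L) return(reads)
  ridx <- rep(hit, nerr[hit])
  pos <- ceiling(stats::runif(length(ridx)) * L[ridx])
  round_of <- sequence(nerr[hit])
  for (r in seq_len(max(nerr))) {
    sel <- round_of == r
    ri <- ridx[sel]; pi <- pos[sel]
    old <- substring(reads[ri], pi, pi)
    oi <- match(old, bases)
    oi[is.na(oi)] <- 1L  # non-ACGT base: overwrite with a random other base
    ni <- ((oi - 1L + sample.int(3L, length(oi), replace = TRUE)) %% 4L) + 1L
    x <- reads[ri]
    substr(x, pi, pi) <- bases[ni]
    reads[ri] <- x
  }
  reads
}

#' Simulate a FASTQ dataset with known duplicate ground truth
#'
#' Draws templates from `reference` per `spec`, amplifies them into exact
#' copies, shuffles the emitted order, writes FASTQ file(s) and computes
#' the ground-truth multiset counts of the emitted dataset (not of the
#' templates: coincidental collisions between distinct templates count as
#' redundancy, exactly as a counting script would see them).
#'
#' @param reference Reference sequence (single character string).
#' @param spec A [sim_spec()].
#' @param out1 Output FASTQ path (mate 1 when paired).
#' @param out2 Mate-2 output path (required when `spec$paired`).
#' @return A `sim_result` list: `files`, `total_reads` (FASTQ records),
#'   `n_units` (reads, or pairs when paired), `n_templates`, and
#'   `ground_truth`, a [count_unique()]-style report over the emitted
#'   units.
#' @export
simulate_reads <- function(reference, spec, out1, out2 = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  G <- nchar(reference)
  L <- spec$read_length
  if (L > G)
    stop("read_length must not exceed the reference length", call. = FALSE)
  if (spec$paired && is.null(out2))
    stop("paired simulation requires out2", call. = FALSE)
  with_local_seed(spec$seed, {
    reads_per_unit <- if (spec$paired) 2L else 1L
    N0 <- max(1L, as.integer(round(spec$coverage * G / (reads_per_unit * L))))
    if (spec$paired) {
      frag <- as.integer(round(stats::rnorm(N0, spec$insert_size_mean,
                                            spec$insert_size_sd)))
      frag <- pmin(pmax(frag, L), G)
      start <- 1L + as.integer(floor(stats::runif(N0) * (G - frag + 1)))
      m1 <- substring(reference, start, start + L - 1L)
      m2 <- substring(reference, start + frag - L, start + frag - 1L)
      m1 <- apply_substitutions(m1, spec$substitution_rate)
      m2 <- apply_substitutions(m2, spec$substitution_rate)
    } else {
      start <- 1L + as.integer(floor(stats::runif(N0) * (G - L + 1)))
      m1 <- substring(reference, start, start + L - 1L)
      m1 <- apply_substitutions(m1, spec$substitution_rate)
    }
    extra <- switch(spec$duplication_model,
                    none = integer(N0),
                    poisson = stats::rpois(N0, spec$dup_rate),
                    geometric = stats::rgeom(N0, spec$dup_rate))
    tmpl <- rep(seq_len(N0), 1L + extra)
    copy <- sequence(1L + extra)
    perm <- sample.int(length(tmpl))
    tmpl <- tmpl[perm]; copy <- copy[perm]
    n_units <- length(tmpl)
    qual <- strrep(spec$quality_char, L)
    ids <- sprintf("sim_t%07d_c%d", tmpl, copy)
    if (spec$paired) {
      s1 <- m1[tmpl]; s2 <- m2[tmpl]
      write_fastq(data.frame(read_id = paste0(ids, "/1"), sequence = s1,
                             plus_line = "", quality = qual), out1)
      write_fastq(data.frame(read_id = paste0(ids, "/2"), sequence = s2,
                             plus_line = "", quality = qual), out2)
      keys <- dedup_key_paired(s1, s2)
    } else {
      s1 <- m1[tmpl]
      write_fastq(data.frame(read_id = ids, sequence = s1, plus_line = "",
                             quality = qual), out1)
      keys <- dedup_key_single(s1)
    }
    structure(list(files = c(out1, out2), total_reads = n_units * reads_per_unit,
                   n_units = n_units, n_templates = N0,
                   ground_truth = count_keys(keys)),
              class = "sim_result")
  })
}

#' Simulate a coverage series
#'
#' Generates one dataset per coverage value from the same reference,
#' deriving dataset seeds as `spec$seed + index` so the series is
#' reproducible as a whole. This mirrors the standard validation design in
#' which the same genome is sequenced at increasing depth (e.g. 100x, 200x,
#' 300x) and a correct duplicate remover must conserve the number of unique
#' reads at every depth.
#'
#' @param reference Reference sequence.
#' @param base_spec A [sim_spec()] whose `coverage` and `seed` are
#'   overridden per dataset.
#' @param coverages Numeric vector of coverages.
#' @param dir Output directory for the FASTQ files.
#' @param prefix File-name prefix.
#' @return List of `sim_result`, one per coverage.
#' @export
coverage_series <- function(reference, base_spec,
                            coverages = c(100, 200, 300),
                            dir = tempdir(), prefix = "sim") {
  stopifnot(inherits(base_spec, "sim_spec"))
  lapply(seq_along(coverages), function(i) {
    spec <- base_spec
    spec$coverage <- coverages[i]
    spec$seed <- base_spec$seed + i
    out1 <- file.path(dir, sprintf("%s_%gx_1.fastq", prefix, coverages[i]))
    out2 <- if (spec$paired)
      file.path(dir, sprintf("%s_%gx_2.fastq", prefix, coverages[i]))
    else NULL
    simulate_reads(reference, spec, out1, out2)
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulated dataset: %d records (%d units, %d templates)\n",
              as.integer(x$total_reads), as.integer(x$n_units),
              as.integer(x$n_templates)))
  cat(sprintf("  files: %s\n", paste(x$files, collapse = ", ")))
  cat("  ground truth: "); print(x$ground_truth)
  invisible(x)
}
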