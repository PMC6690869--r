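Package: dedupcf
Title: Exact Duplicate Read Removal for FASTQ Using Cuckoo Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Streaming removal of exact duplicate reads (PCR redundancy)
    from single-end and paired-end FASTQ files of any platform and mixed
    read lengths, using a compact partial-key cuckoo filter with no false
    negatives, so every duplicate is found while memory stays proportional
    to the fingerprint table rather than to the reads. Includes an exact
    hash-set mode for verification, a synthetic read simulator with
    controlled PCR-duplication and ground-truth duplicate counts, a
    unique-read counter for validating that deduplication conserves the
    number of distinct reads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
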