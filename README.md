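# dedupcf

Exact duplicate-read removal for FASTQ files using a partial-key cuckoo
filter.

## The problem

Library amplification (PCR) leaves next-generation sequencing datasets
with redundant reads: exact copies of the same fragment that inflate
coverage, bias *de novo* assembly and variant calling, and waste compute
downstream. Removing them is a standard preprocessing step, but tools
that sort or hash the full read set need memory proportional to the data,
and several fail outright on single-end libraries, mixed read lengths or
orphaned mates.

`dedupcf` streams single-end or paired-end FASTQ (plain or gzip, any
platform, uniform or mixed read lengths) and keeps the first occurrence
of every distinct sequence (or mate-pair of sequences), using a **cuckoo
filter** for membership instead of an exact set.

## The structure at its core

A cuckoo filter stores, for each item `x`, only a short fingerprint
`fp(x)` of `f` bits in one of two candidate buckets of `b` slots each:

    i1 = hash(x) mod m
    i2 = i1 XOR (hash(fp(x)) mod m)

With `m` a power of two the XOR mapping is an involution, so either
bucket can compute the other from the stored fingerprint alone — this is
what makes cuckoo-style eviction (relocating residents to their alternate
bucket, up to `max_kicks` times) possible without storing the keys.

The filter **never returns a false negative** for a retained item, so no
duplicate is ever missed; it may return a false positive at rate
≈ `2b / 2^f` (about 1.2 × 10⁻⁴ at the defaults `f = 16`, `b = 4`), which
can very rarely discard a unique read. An exact hash-set mode
(`mode = "exact"`) with zero error in both directions is built in for
verification, and a full filter is never an error: additional filters are
chained transparently.

The package also ships the two instruments needed to validate a duplicate
remover at desk scale: a read simulator with a controlled PCR-duplication
model that reports the exact ground-truth redundancy of what it emitted,
and a unique-read counter (`count_unique()`) that checks the conservation
property — deduplication must leave every read occurring exactly once
while conserving the raw dataset's number of distinct reads.

## Worked example

```r
library(dedupcf)

ref  <- simulate_reference(1e4, seed = 7)
spec <- sim_spec(read_length = 100, coverage = 20,
                 duplication_model = "poisson", dup_rate = 1, seed = 3)
sim  <- simulate_reads(ref, spec, "sim.fastq")
sim
#> simulated dataset: 3961 records (3961 units, 2000 templates)
#>   files: sim.fastq
#>   ground truth: total 3961 | distinct 1922 | appear-once 696 | redundant 2039

rep <- dedup_fastq("sim.fastq", "dedup.fastq", mode = "cuckoo")
rep
#> duplicate-removal report (cuckoo mode)
#>   total reads:   3961
#>   kept reads:    1922
#>   removed reads: 2039 (51.48%)
#>   filters chained: 1

count_unique("dedup.fastq")
#> total 1922 | distinct 1922 | appear-once 1922 | redundant 0
```

Every template got on average one PCR copy (`dup_rate = 1`), so about
half the reads are redundant; the filter removed exactly the 2039
ground-truth redundant reads, and the output conserves the raw dataset's
1922 distinct reads, each now appearing once.

The same operations are available from a shell via the installed
`exec/dedupcf` script:

```sh
dedupcf dedup --in1 reads_1.fastq.gz --in2 reads_2.fastq.gz \
        --out1 dedup_1.fastq.gz --out2 dedup_2.fastq.gz --report report.json
dedupcf simulate --ref-length 100000 --coverage 100 --out1 sim.fastq
dedupcf count-unique --in1 dedup_1.fastq.gz --in2 dedup_2.fastq.gz
```

Exit codes: 0 success, 1 usage error, 2 format/pairing error, 3 I/O
error.

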