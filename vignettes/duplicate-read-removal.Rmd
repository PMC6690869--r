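---
title: "Removing duplicate reads with a cuckoo filter: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing duplicate reads with a cuckoo filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dedupcf)
```

## What counts as a duplicate

`dedupcf` removes *exact* duplicates: two single-end reads are duplicates
when their sequences are byte-identical after uppercasing; two read pairs
are duplicates when mate 1 matches mate 1 and mate 2 matches mate 2.
Headers and quality strings never participate. This is the duplicate
definition under which PCR amplification artifacts arise — an amplified
fragment yields copies with identical sequence — and it is the definition
the validation instruments in this package measure.

Three deliberate consequences of this definition:

* **No strand canonicalisation.** A read and its reverse complement are
  different sequences. Fragments sequenced from opposite strands are not
  merged.
* **Mate order matters.** A pair `(A, B)` and its swap `(B, A)` are
  distinct. Pair keys are `upper(seq1) || 0x1F || upper(seq2)`; the
  separator byte (which cannot occur in sequence text) prevents
  concatenation collisions such as `("AC","GT")` vs `("ACG","T")`.
* **`N` bases are literal.** Reads containing ambiguity codes are
  deduplicated like any other read.

Near-duplicate clustering (mismatch-tolerant, prefix-based, or
alignment-based) is out of scope.

## The membership structure

The engine streams reads in file order and keeps a read iff its key has
not been seen. Membership is answered by a partial-key cuckoo filter: a
table of `m` buckets × `b` slots, each slot holding one `f`-bit
fingerprint. An item `x` may live in

$$i_1 = h(x) \bmod m, \qquad i_2 = i_1 \oplus (h(\mathrm{fp}(x)) \bmod m),$$

and because `m` is a power of two the XOR mapping is an involution:
from either bucket, the alternate is recoverable using only the stored
fingerprint. Inserting into a full pair of buckets evicts a random
resident to its alternate bucket, cascading up to `max_kicks` times; a
failed insert is rolled back (the table is left holding its original
multiset) and reported, never raised as an error.

Properties that the tests assert directly:

* **No false negatives** for inserted-and-not-deleted items, the
  property that guarantees every true duplicate is removed.
* **False positives** at rate ≈ `2b/2^f` when the table is full (lower at
  partial load): the filter may claim membership for a never-inserted key
  whose fingerprint collides in a candidate bucket. In deduplication this
  discards a unique read. At the defaults (`f = 16`, `b = 4`) the rate is
  about 1.2 × 10⁻⁴ per distinct read; at dataset sizes of 10⁶–10⁷ reads
  the expected loss is a few hundred reads at most, and measured losses
  in the test suite are single digits.
* **Deletion** removes one matching fingerprint (multiset semantics).
  Deleting a never-inserted item can remove a colliding item's
  fingerprint and manufacture a false negative — the standard hazard,
  documented on `cf_delete()`.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `fingerprint_bits` (`f`) | 16 | bits per fingerprint; FP rate ≈ `2b/2^f` |
| `bucket_slots` (`b`) | 4 | slots per bucket; with 2 candidate buckets, loads above 95% are routinely reachable |
| `num_buckets` (`m`) | sized | smallest power of two with `m·b ≥ expected/0.90` |
| `max_kicks` | 500 | eviction-walk length before declaring the filter full |
| `seed` | 42 | drives hashing and eviction; fixed seed ⇒ byte-reproducible runs |

The hash is a seeded 64-bit FNV-1a with a 64-bit avalanche finaliser;
fingerprints use the same hash under a fixed seed tweak, and a masked
value of 0 is remapped to 1 so that 0 can mark empty slots with a
branch-free test.

### Sizing and the filter chain

When the caller gives no `expected_reads` hint the first filter is sized
for 2²⁰ keys (counting reads up front would require a second pass over
possibly gzipped input). A full filter cannot be grown in place — the
fingerprints cannot be rehashed without the original keys — so the engine
*chains* a fresh filter of the same geometry: all filters answer
membership, new keys go into the newest. The no-false-negative contract
survives chaining; the false-positive rate sums over filters, which is
why the report records `filters_chained`.

### Exact mode

`mode = "exact"` replaces the filter with a hash set of full keys: zero
error in both directions, memory proportional to distinct reads. It is
the verification oracle in the test suite (checked against R's
`duplicated()` independently) and the right choice when the dataset fits
in memory and any loss is unacceptable.

## FASTQ handling

The reader accepts the strict 4-line dialect only, plain or gzipped
(autodetected by magic bytes). Wrapped multi-line records are rejected
rather than repaired — modern FASTQ is 4-line, and silent repair hides
corruption. Truncation, marker, and length errors name the offending
record. Pairing is positional (record *k* with record *k*): synchronized
pair files guarantee it, it needs O(1) memory, and no header convention
has to be parsed. Unequal files are governed by an explicit
`orphan_policy`: `"error"` (default — surprises should be loud) or
`"drop_tail"`, which keeps the pairable prefix and reports how many
orphans were dropped. Output preserves sequence case and the text after
`+`; a read–write–read round trip is the identity.

## The simulator and what it does (not) emulate

`simulate_reads()` stands in for a full read simulator where ground truth
matters more than platform realism:

* templates are drawn uniformly from the forward strand of the reference,
  `N0 = round(coverage · G / L)` of them (halved for pairs, whose
  fragment lengths are Gaussian);
* substitution errors are applied i.i.d. per base (default rate 0.005, a
  typical short-read order of magnitude), **before** amplification;
* each template is then emitted `1 + extra` times, with `extra` Poisson
  or geometric — so PCR copies are byte-identical to their template,
  matching the exact-identity duplicate definition;
* the emitted order is globally shuffled, and the **ground truth** is
  computed by multiset-counting the duplicate keys of what was actually
  written, so coincidental collisions between distinct templates count as
  redundancy exactly as any counting script would see them.

Deliberately not emulated: platform-specific quality/error profiles,
indels, homopolymer errors, reverse-strand sampling, optical duplicates,
amplicon bias. Mate 2 of a pair is the forward-strand window at the far
end of the fragment (no reverse complement): since the duplicate
definition does not canonicalise strands, orientation adds nothing
testable. Qualities are a constant character (default `I`) because
deduplication ignores them. Passing tests therefore demonstrate
correctness of duplicate identification and removal under exact-copy
redundancy — not robustness to error-model realism, which affects only
how many *near*-duplicates (never targeted) a real library would contain.

## Validation design

The acceptance tests reproduce, at desk scale, the standard validation
logic for duplicate removers:

1. **Ground-truth recovery** — over 102 seeded datasets (10³–10⁴
   templates; duplication λ ∈ {0, 0.3, 1}; single- and paired-end),
   exact-mode removal equals the simulator's redundant-read count
   exactly, and the output contains only once-occurring reads.
2. **Filter fidelity** — on the same suite, cuckoo mode at `f = 16`
   never removes fewer reads than exact mode (no duplicate escapes), and
   its extra removals stay within the 99.9% binomial bound at rate
   `2b/2^f`; at `f = 8` false positives are expected and the measured
   extra-removal rate must be positive yet ≤ 1.5 × `2b/2^f`. Filters are
   sized to the dataset for these runs so the bound is exercised at a
   realistic load.
3. **Microproperties** — 10⁵ insert/lookup trials without a false
   negative; empirical FP rates within 1.5 × the analytic rate for
   `f ∈ {8, 12, 16}` at 90% load; median achievable load ≥ 0.90 over 20
   seeds (measured ≈ 0.97); XOR involution over 10⁴ items.
4. **Coverage series** — 3 synthetic references (10⁵ bases) × coverages
   {100, 200, 300} with Poisson(0.5) amplification: on all nine datasets
   exact-mode removal conserves the distinct-read count, the property
   separating correct tools from over-aggressive ones.
5. **Robustness** — round-trip identity, defined errors for truncated
   records and orphaned mates, gzip transparency, and byte-identical
   reruns under a fixed seed.

Problem sizes (10³–10⁴ templates per suite dataset, 10⁵-base references
for the coverage series) were chosen as the smallest at which all the
statistical bounds above are sharp; the same properties are
scale-invariant upward. `scripts/acceptance.R` re-measures the headline
numbers from scratch under any `--seed`.

## Numerical and degenerate-input choices

* `removed_pct = 100 · removed / total`, defined as 0 for empty input;
  printed to two decimals.
* A single-bucket table (`m = 1`) is legal: both candidate indices are 0.
* Fingerprint width is capped at 32 bits (stored in 32-bit slots;
  returned to R as doubles, which hold them exactly).
* Dataset seeds in `coverage_series()` derive as `seed + index`, so a
  series is reproducible as a whole without making its members identical.
* Chained filters take the first filter's geometry with the seed offset
  by the chain index, so their eviction walks differ.

## Known limitations

* Cuckoo mode can discard a unique read on a fingerprint collision; use
  `mode = "exact"` when that is unacceptable.
* The whole distinct-key set of exact mode lives in memory; cuckoo mode's
  memory is the filter table(s) only.
* Pairing is positional; files that are unsynchronised but equal-length
  are undetectable by construction (no header validation is attempted).
* The simulator's ground truth is defined over emitted sequences, not
  templates: it is the right reference for a deduplicator, but it is not
  a per-template amplification log.
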