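// Partial-key cuckoo filter core and exact-set membership backend.
//
// Hashing: FNV-1a 64-bit over the key bytes, seeded by XORing the offset
// basis with an avalanche-finalised seed, and passed through the 64-bit
// MurmurHash3 finaliser so that low bits are uniform. The same hash family
// (with a fixed seed tweak) derives fingerprints, so one seed controls the
// whole filter reproducibly.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static inline uint64_t hash64(const char* s, size_t n, uint64_t seed) {
  uint64_t h = 0xcbf29ce484222325ULL ^ fmix64(seed);
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(uint8_t)s[i];
    h *= 0x100000001b3ULL;
  }
  return fmix64(h);
}

// seed tweak separating fingerprint derivation from bucket indexing
static const uint64_t FP_TWEAK = 0x9E3779B97F4A7C15ULL;

static inline uint64_t fp_mask(int f) {
  return (f >= 64) ? ~0ULL : ((1ULL << f) - 1ULL);
}

static inline uint32_t make_fp(const char* s, size_t n, int f, uint64_t seed) {
  uint64_t fp = hash64(s, n, seed ^ FP_TWEAK) & fp_mask(f);
  if (fp == 0) fp = 1;  // 0 is the empty-slot sentinel
  return (uint32_t)fp;
}

struct CuckooFilter {
  int f;             // fingerprint bits
  int b;             // slots per bucket
  uint64_t m;        // buckets (power of two)
  int max_kicks;
  uint64_t seed;
  std::vector<uint32_t> table;  // m*b slots, 0 = empty
  uint64_t n_items;
  uint64_t rng;      // splitmix64 state for eviction choices

  CuckooFilter(int f_, int b_, uint64_t m_, int mk_, uint64_t seed_)
    : f(f_), b(b_), m(m_), max_kicks(mk_), seed(seed_),
      table((size_t)m_ * (size_t)b_, 0u), n_items(0),
      rng(fmix64(seed_ ^ 0xD1B54A32D192ED03ULL)) {}

  inline uint64_t next_rand() {
    rng += 0x9E3779B97F4A7C15ULL;
    return fmix64(rng);
  }

  inline uint64_t bucket1(const char* s, size_t n) const {
    return hash64(s, n, seed) & (m - 1);
  }

  inline uint64_t alt_bucket(uint64_t i, uint32_t fp) const {
    // hash the fingerprint as 8 little-endian bytes
    unsigned char buf[8];
    uint64_t v = fp;
    for (int k = 0; k < 8; ++k) buf[k] = (unsigned char)((v >> (8 * k)) & 0xFF);
    return i ^ (hash64((const char*)buf, 8, seed) & (m - 1));
  }

  inline int find_in_bucket(uint64_t i, uint32_t fp) const {
    const uint32_t* row = &table[(size_t)i * b];
    for (int s = 0; s < b; ++s)
      if (row[s] == fp) return s;
    return -1;
  }

  inline int empty_slot(uint64_t i) const {
    const uint32_t* row = &table[(size_t)i * b];
    for (int s = 0; s < b; ++s)
      if (row[s] == 0) return s;
    return -1;
  }

  bool contains_key(const char* s, size_t n) const {
    uint32_t fp = make_fp(s, n, f, seed);
    uint64_t i1 = bucket1(s, n);
    if (find_in_bucket(i1, fp) >= 0) return true;
    uint64_t i2 = alt_bucket(i1, fp);
    return find_in_bucket(i2, fp) >= 0;
  }

  bool insert_key(const char* s, size_t n) {
    uint32_t fp = make_fp(s, n, f, seed);
    uint64_t i1 = bucket1(s, n);
    uint64_t i2 = alt_bucket(i1, fp);
    int sl = empty_slot(i1);
    if (sl >= 0) { table[(size_t)i1 * b + sl] = fp; ++n_items; return true; }
    sl = empty_slot(i2);
    if (sl >= 0) { table[(size_t)i2 * b + sl] = fp; ++n_items; return true; }
    // relocation loop; remember the swap path so a failed insert can be
    // rolled back, leaving the table holding its original multiset
    uint64_t i = (next_rand() & 1) ? i2 : i1;
    uint32_t cur = fp;
    std::vector<size_t> path;
    path.reserve(max_kicks);
    for (int k = 0; k < max_kicks; ++k) {
      size_t slot = (size_t)i * b + (size_t)(next_rand() % (uint64_t)b);
      std::swap(cur, table[slot]);
      path.push_back(slot);
      i = alt_bucket(i, cur);
      int e = empty_slot(i);
      if (e >= 0) {
        table[(size_t)i * b + e] = cur;
        ++n_items;
        return true;
      }
    }
    // undo the evictions in reverse order
    for (size_t k = path.size(); k-- > 0;) std::swap(cur, table[path[k]]);
    return false;
  }

  bool delete_key(const char* s, size_t n) {
    uint32_t fp = make_fp(s, n, f, seed);
    uint64_t i1 = bucket1(s, n);
    int sl = find_in_bucket(i1, fp);
    if (sl >= 0) { table[(size_t)i1 * b + sl] = 0; --n_items; return true; }
    uint64_t i2 = alt_bucket(i1, fp);
    sl = find_in_bucket(i2, fp);
    if (sl >= 0) { table[(size_t)i2 * b + sl] = 0; --n_items; return true; }
    return false;
  }
};

static inline CuckooFilter* get_cf(SEXP xp) {
  Rcpp::XPtr<CuckooFilter> p(xp);
  return p.get();
}

static inline const char* key_chars(const CharacterVector& x, R_xlen_t i,
                                    size_t* n) {
  SEXP s = STRING_ELT(x, i);
  if (s == NA_STRING) stop("keys must not be NA");
  *n = (size_t)LENGTH(s);
  if (*n == 0) stop("keys must be non-empty byte strings");
  return CHAR(s);
}

// [[Rcpp::export(name = ".cf_new")]]
SEXP cf_new(int f, int b, double m, int max_kicks, double seed) {
  CuckooFilter* cf =
    new CuckooFilter(f, b, (uint64_t)m, max_kicks, (uint64_t)seed);
  return Rcpp::XPtr<CuckooFilter>(cf, true);
}

// [[Rcpp::export(name = ".cf_info")]]
List cf_info(SEXP xp) {
  CuckooFilter* cf = get_cf(xp);
  return List::create(
    _["fingerprint_bits"] = cf->f, _["bucket_slots"] = cf->b,
    _["num_buckets"] = (double)cf->m, _["max_kicks"] = cf->max_kicks,
    _["seed"] = (double)cf->seed, _["item_count"] = (double)cf->n_items);
}

// [[Rcpp::export(name = ".cf_insert")]]
LogicalVector cf_insert_cpp(SEXP xp, CharacterVector keys) {
  CuckooFilter* cf = get_cf(xp);
  R_xlen_t n = keys.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(keys, i, &len);
    out[i] = cf->insert_key(s, len);
  }
  return out;
}

// [[Rcpp::export(name = ".cf_contains")]]
LogicalVector cf_contains_cpp(SEXP xp, CharacterVector keys) {
  CuckooFilter* cf = get_cf(xp);
  R_xlen_t n = keys.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(keys, i, &len);
    out[i] = cf->contains_key(s, len);
  }
  return out;
}

// [[Rcpp::export(name = ".cf_delete")]]
LogicalVector cf_delete_cpp(SEXP xp, CharacterVector keys) {
  CuckooFilter* cf = get_cf(xp);
  R_xlen_t n = keys.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(keys, i, &len);
    out[i] = cf->delete_key(s, len);
  }
  return out;
}

// Check-then-insert across a chain of filters: each key is looked up in
// every filter; if absent it is inserted into the last one. Stops at the
// first failed insert (filter full) and reports how many keys were handled
// so the caller can extend the chain and resume.
// [[Rcpp::export(name = ".cf_check_insert_chain")]]
List cf_check_insert_chain(List ptrs, CharacterVector keys) {
  int nf = ptrs.size();
  std::vector<CuckooFilter*> fs(nf);
  for (int j = 0; j < nf; ++j) fs[j] = get_cf(ptrs[j]);
  CuckooFilter* last = fs[nf - 1];
  R_xlen_t n = keys.size();
  LogicalVector keep(n, NA_LOGICAL);
  R_xlen_t processed = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(keys, i, &len);
    bool found = false;
    for (int j = 0; j < nf && !found; ++j) found = fs[j]->contains_key(s, len);
    if (found) {
      keep[i] = false;
      ++processed;
      continue;
    }
    if (!last->insert_key(s, len)) break;  // full: caller chains a new filter
    keep[i] = true;
    ++processed;
  }
  return List::create(_["keep"] = keep, _["processed"] = (double)processed);
}

// [[Rcpp::export(name = ".cf_fingerprint")]]
NumericVector cf_fingerprint(CharacterVector items, int f, double seed) {
  R_xlen_t n = items.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(items, i, &len);
    out[i] = (double)make_fp(s, len, f, (uint64_t)seed);
  }
  return out;
}

// [[Rcpp::export(name = ".cf_buckets")]]
List cf_buckets(CharacterVector items, double m, int f, double seed) {
  R_xlen_t n = items.size();
  uint64_t mm = (uint64_t)m;
  NumericVector i1(n), i2(n), fp(n);
  CuckooFilter tmp(f, 1, mm, 1, (uint64_t)seed);  // reuse index helpers
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(items, i, &len);
    uint32_t v = make_fp(s, len, f, (uint64_t)seed);
    uint64_t b1 = tmp.bucket1(s, len);
    fp[i] = (double)v;
    i1[i] = (double)b1;
    i2[i] = (double)tmp.alt_bucket(b1, v);
  }
  return List::create(_["i1"] = i1, _["i2"] = i2, _["fingerprint"] = fp);
}

// [[Rcpp::export(name = ".cf_alt_index")]]
NumericVector cf_alt_index(NumericVector idx, NumericVector fp, double m,
                           int f, double seed) {
  CuckooFilter tmp(f, 1, (uint64_t)m, 1, (uint64_t)seed);
  R_xlen_t n = idx.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (double)tmp.alt_bucket((uint64_t)idx[i], (uint32_t)fp[i]);
  return out;
}

// ---- exact-set backend (hash set over full keys) ----

// [[Rcpp::export(name = ".exact_new")]]
SEXP exact_new() {
  auto* s = new std::unordered_set<std::string>();
  return Rcpp::XPtr<std::unordered_set<std::string>>(s, true);
}

// [[Rcpp::export(name = ".exact_check_insert")]]
LogicalVector exact_check_insert(SEXP xp, CharacterVector keys) {
  Rcpp::XPtr<std::unordered_set<std::string>> set(xp);
  R_xlen_t n = keys.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    size_t len;
    const char* s = key_chars(keys, i, &len);
    out[i] = set->insert(std::string(s, len)).second;
  }
  return out;
}

// [[Rcpp::export(name = ".exact_size")]]
double exact_size(SEXP xp) {
  Rcpp::XPtr<std::unordered_set<std::string>> set(xp);
  return (double)set->size();
}
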