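// Canonical k-mer engine.
//
// K-mers (k <= 63) are 2-bit packed into unsigned 128-bit integers and a
// k-mer set is a sorted, deduplicated vector of packed canonical forms
// (canonical = lexicographic min of a k-mer and its reverse complement).
// Membership tests use binary search; set algebra uses merge scans.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

struct KmerSet {
  int k;
  std::vector<u128> v;  // sorted, unique
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char DECODE[4] = {'A', 'C', 'G', 'T'};

static inline u128 kmask(int k) {
  return (((u128)1) << (2 * k)) - 1;
}

// Enumerate canonical k-mers of seq; cb(start, kmer) for each valid window.
template <typename F>
static void scan_canonical(const char *s, size_t n, int k, F cb) {
  if ((size_t)k > n) return;
  u128 fwd = 0, rc = 0;
  const u128 mask = kmask(k);
  const int shift = 2 * (k - 1);
  int len = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { len = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128)c) & mask;
    rc = (rc >> 2) | (((u128)(3 - c)) << shift);
    if (++len >= k) {
      u128 canon = fwd < rc ? fwd : rc;
      cb(i + 1 - (size_t)k, canon);
    }
  }
}

static KmerSet *get_set(SEXP xp) {
  Rcpp::XPtr<KmerSet> p(xp);
  return p.get();
}

static SEXP wrap_set(KmerSet *ks) {
  Rcpp::XPtr<KmerSet> p(ks, true);
  return p;
}

// [[Rcpp::export]]
SEXP cpp_kmer_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 63) stop("k must be in 1..63");
  KmerSet *ks = new KmerSet();
  ks->k = k;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const char *s = CHAR(STRING_ELT(seqs, j));
    size_t n = LENGTH(STRING_ELT(seqs, j));
    scan_canonical(s, n, k, [&](size_t, u128 km) { ks->v.push_back(km); });
  }
  std::sort(ks->v.begin(), ks->v.end());
  ks->v.erase(std::unique(ks->v.begin(), ks->v.end()), ks->v.end());
  ks->v.shrink_to_fit();
  return wrap_set(ks);
}

// [[Rcpp::export]]
int cpp_kmer_k(SEXP xp) { return get_set(xp)->k; }

// [[Rcpp::export]]
double cpp_kmer_size(SEXP xp) { return (double)get_set(xp)->v.size(); }

// [[Rcpp::export]]
SEXP cpp_kmer_setdiff(SEXP xa, SEXP xb) {
  KmerSet *a = get_set(xa), *b = get_set(xb);
  if (a->k != b->k) stop("k-mer sets have different k");
  KmerSet *out = new KmerSet();
  out->k = a->k;
  std::set_difference(a->v.begin(), a->v.end(), b->v.begin(), b->v.end(),
                      std::back_inserter(out->v));
  return wrap_set(out);
}

// [[Rcpp::export]]
SEXP cpp_kmer_intersect(SEXP xa, SEXP xb) {
  KmerSet *a = get_set(xa), *b = get_set(xb);
  if (a->k != b->k) stop("k-mer sets have different k");
  KmerSet *out = new KmerSet();
  out->k = a->k;
  std::set_intersection(a->v.begin(), a->v.end(), b->v.begin(), b->v.end(),
                        std::back_inserter(out->v));
  return wrap_set(out);
}

// [[Rcpp::export]]
SEXP cpp_kmer_union(SEXP xa, SEXP xb) {
  KmerSet *a = get_set(xa), *b = get_set(xb);
  if (a->k != b->k) stop("k-mer sets have different k");
  KmerSet *out = new KmerSet();
  out->k = a->k;
  std::set_union(a->v.begin(), a->v.end(), b->v.begin(), b->v.end(),
                 std::back_inserter(out->v));
  return wrap_set(out);
}

static std::string decode_kmer(u128 km, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = DECODE[(int)(km & 3)];
    km >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_kmer_decode(SEXP xp) {
  KmerSet *ks = get_set(xp);
  if (ks->v.size() > (size_t)1e7) stop("k-mer set too large to decode");
  CharacterVector out(ks->v.size());
  for (size_t i = 0; i < ks->v.size(); ++i)
    out[i] = decode_kmer(ks->v[i], ks->k);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_kmer_from_strings(CharacterVector kmers, int k) {
  if (k < 1 || k > 63) stop("k must be in 1..63");
  KmerSet *ks = new KmerSet();
  ks->k = k;
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const char *s = CHAR(STRING_ELT(kmers, j));
    size_t n = LENGTH(STRING_ELT(kmers, j));
    if (n != (size_t)k) { delete ks; stop("k-mer string of wrong length"); }
    bool seen = false;
    scan_canonical(s, n, k, [&](size_t, u128 km) { ks->v.push_back(km); seen = true; });
    if (!seen) { delete ks; stop("k-mer string contains non-ACGT characters"); }
  }
  std::sort(ks->v.begin(), ks->v.end());
  ks->v.erase(std::unique(ks->v.begin(), ks->v.end()), ks->v.end());
  return wrap_set(ks);
}

// [[Rcpp::export]]
LogicalVector cpp_kmer_contains(SEXP xp, CharacterVector kmers) {
  KmerSet *ks = get_set(xp);
  LogicalVector out(kmers.size());
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const char *s = CHAR(STRING_ELT(kmers, j));
    size_t n = LENGTH(STRING_ELT(kmers, j));
    bool hit = false, valid = false;
    if (n == (size_t)ks->k)
      scan_canonical(s, n, ks->k, [&](size_t, u128 km) {
        valid = true;
        hit = std::binary_search(ks->v.begin(), ks->v.end(), km);
      });
    out[j] = valid ? hit : NA_LOGICAL;
  }
  return out;
}

// Per-window sums of specific-k-mer coverage over one chromosome.
// starts = false: each matching k-mer start adds 1 to the per-base depth of
// the k bases it covers; window sum = total base depth in the window.
// starts = true: window sum = number of matching k-mer start positions.
// [[Rcpp::export]]
NumericVector cpp_window_cov_sums(CharacterVector seq, SEXP xp, double width,
                                  bool starts) {
  KmerSet *ks = get_set(xp);
  const char *s = CHAR(STRING_ELT(seq, 0));
  size_t n = LENGTH(STRING_ELT(seq, 0));
  size_t w = (size_t)width;
  size_t nwin = n == 0 ? 1 : (n + w - 1) / w;
  NumericVector out((R_xlen_t)nwin);
  if (starts) {
    scan_canonical(s, n, ks->k, [&](size_t pos, u128 km) {
      if (std::binary_search(ks->v.begin(), ks->v.end(), km))
        out[pos / w] += 1.0;
    });
    return out;
  }
  std::vector<int32_t> diff(n + 1, 0);
  scan_canonical(s, n, ks->k, [&](size_t pos, u128 km) {
    if (std::binary_search(ks->v.begin(), ks->v.end(), km)) {
      diff[pos] += 1;
      diff[pos + (size_t)ks->k] -= 1;
    }
  });
  int64_t depth = 0;
  for (size_t i = 0; i < n; ++i) {
    depth += diff[i];
    out[i / w] += (double)depth;
  }
  return out;
}

// Identity-by-state variation counts: one variation per maximal run of
// consecutive valid k-mer start positions whose canonical k-mer is absent
// from the query set; a run is attributed to the window containing its
// start. Positions whose k-mer spans a non-ACGT base are skipped and
// terminate any open run.
// [[Rcpp::export]]
IntegerVector cpp_window_variations(CharacterVector seq, SEXP xp, double width) {
  KmerSet *ks = get_set(xp);
  const char *s = CHAR(STRING_ELT(seq, 0));
  size_t n = LENGTH(STRING_ELT(seq, 0));
  size_t w = (size_t)width;
  size_t nwin = n == 0 ? 1 : (n + w - 1) / w;
  IntegerVector out((R_xlen_t)nwin);
  bool in_run = false;
  size_t expect = 0;  // next position that continues the current run
  scan_canonical(s, n, ks->k, [&](size_t pos, u128 km) {
    bool present = std::binary_search(ks->v.begin(), ks->v.end(), km);
    if (in_run && pos != expect) in_run = false;  // gap of invalid positions
    if (!present) {
      if (!in_run) {
        out[pos / w] += 1;
        in_run = true;
      }
      expect = pos + 1;
    } else {
      in_run = false;
    }
  });
  return out;
}
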