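#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding A=0 C=1 G=2 T=3; k-mers are packed into the low 2k bits of
// a uint64 with the leftmost base in the highest bits, so integer comparison
// equals lexicographic comparison under A<C<G<T.

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_bits(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

// Stream canonical k-mers from a set of sequences into a count table.
// k-mers containing any non-ACGT character are skipped.
static void stream_kmers(const CharacterVector &seqs, int k,
                         std::unordered_map<uint64_t, uint32_t> &tab,
                         double &total) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP s_ = STRING_ELT(seqs, i);
    const char *s = CHAR(s_);
    int len = LENGTH(s_);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_rc);
      if (++run >= k) {
        ++tab[fwd < rev ? fwd : rev];
        total += 1.0;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool keep_table) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  double total = 0.0;
  stream_kmers(seqs, k, tab, total);

  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : tab) hist[kv.second] += 1.0;
  std::vector<uint32_t> covs;
  covs.reserve(hist.size());
  for (const auto &kv : hist) covs.push_back(kv.first);
  std::sort(covs.begin(), covs.end());
  IntegerVector coverage(covs.size());
  NumericVector count(covs.size());
  for (size_t i = 0; i < covs.size(); ++i) {
    coverage[i] = (int)covs[i];
    count[i] = hist[covs[i]];
  }
  List out = List::create(_["coverage"] = coverage, _["count"] = count,
                          _["total_kmers"] = total);
  if (keep_table) {
    R_xlen_t n = (R_xlen_t)tab.size();
    CharacterVector km(n);
    NumericVector ct(n);
    std::string buf((size_t)k, 'A');
    R_xlen_t idx = 0;
    for (const auto &kv : tab) {
      uint64_t v = kv.first;
      for (int p = k - 1; p >= 0; --p) { buf[(size_t)p] = BITS2BASE[v & 3ULL]; v >>= 2; }
      km[idx] = buf;
      ct[idx] = kv.second;
      ++idx;
    }
    out["kmer"] = km;
    out["kmer_count"] = ct;
  }
  return out;
}

// Delete the 2 bits of position p (0-based from the left) from a packed k-mer.
static inline uint64_t delete_pos(uint64_t v, int p, int k) {
  int s = 2 * (k - 1 - p);                     // bit offset of position p
  uint64_t lower = v & ((s > 0) ? ((1ULL << s) - 1) : 0ULL);
  uint64_t upper = (p > 0) ? (v >> (s + 2)) : 0ULL;
  return (upper << s) | lower;
}

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[a] = b; }
};

// Group canonical k-mers that differ at exactly one aligned position (same
// flanks), in either relative orientation. Returns a 1-based family id per
// input k-mer, or NA for singletons. Families are connected components of the
// one-substitution graph.
// [[Rcpp::export]]
IntegerVector cpp_het_families(CharacterVector kmers, int k) {
  if (k < 3 || k > 29) stop("family extraction supports 3 <= k <= 29");
  int n = kmers.size();
  std::vector<uint64_t> enc((size_t)n), rc((size_t)n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer length mismatch");
    uint64_t v = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) stop("non-ACGT base in k-mer table");
      v = (v << 2) | (uint64_t)b;
    }
    enc[(size_t)i] = v;
    rc[(size_t)i] = revcomp_bits(v, k);
  }

  // key = masked (position-deleted) sequence in the low 2(k-1) bits, with the
  // deleted position index in the bits above; canonical over the two strands.
  const int posshift = 2 * (k - 1);
  std::unordered_map<uint64_t, int> first;
  first.reserve((size_t)n * (size_t)k);
  DSU dsu(n);
  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < k; ++p) {
      uint64_t k1 = delete_pos(enc[(size_t)i], p, k) | ((uint64_t)p << posshift);
      int q = k - 1 - p;
      uint64_t k2 = delete_pos(rc[(size_t)i], q, k) | ((uint64_t)q << posshift);
      uint64_t key = std::min(k1, k2);
      auto it = first.find(key);
      if (it == first.end()) first.emplace(key, i);
      else dsu.unite(i, it->second);
    }
  }

  std::unordered_map<int, int> root2id;
  std::vector<int> sizes((size_t)n, 0);
  for (int i = 0; i < n; ++i) ++sizes[(size_t)dsu.find(i)];
  IntegerVector fam(n, NA_INTEGER);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int r = dsu.find(i);
    if (sizes[(size_t)r] < 2) continue;
    auto it = root2id.find(r);
    int id;
    if (it == root2id.end()) { id = ++next_id; root2id.emplace(r, id); }
    else id = it->second;
    fam[i] = id;
  }
  return fam;
}

// Hamming distance between two equal-length DNA strings (used by tests and
// the read-simulator truth checks); -1 on length mismatch.
// [[Rcpp::export]]
IntegerVector cpp_mismatch_count(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sa = STRING_ELT(a, i % a.size());
    SEXP sb = STRING_ELT(b, i % b.size());
    if (LENGTH(sa) != LENGTH(sb)) { out[i] = -1; continue; }
    const char *pa = CHAR(sa), *pb = CHAR(sb);
    int len = LENGTH(sa), d = 0;
    for (int j = 0; j < len; ++j) if (pa[j] != pb[j]) ++d;
    out[i] = d;
  }
  return out;
}
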