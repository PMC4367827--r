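// Exact k-mer machinery: counting, histograms, greedy extension, and
// edit-distance-1 neighbourhood sums.  k-mers are packed 2 bits per base
// (A=0, C=1, G=2, T=3, first base in the most significant bits) so k <= 31.
// Windows containing a non-ACGT character are skipped, never corrected.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_packed(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static inline bool encode_kmer(const char *s, int k, uint64_t &out) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    x = (x << 2) | (uint64_t)b;
  }
  out = x;
  return true;
}

typedef std::unordered_map<uint64_t, double> KmerMap;

// Count k-mers of all sequences into `m`.  canonical: merge a k-mer with its
// reverse complement under the lexicographically (= numerically) smaller key.
static void count_into(const CharacterVector &seqs, int k, bool canonical,
                       KmerMap &m) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *s = CHAR(STRING_ELT(seqs, si));
    int n = (int)LENGTH(STRING_ELT(seqs, si));
    if (n < k) continue;
    uint64_t x = 0;
    int run = 0;  // length of current valid (ACGT) run
    for (int i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; x = 0; continue; }
      x = ((x << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t key = x;
        if (canonical) {
          uint64_t rc = revcomp_packed(x, k);
          if (rc < key) key = rc;
        }
        m[key] += 1.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  if (k <= 0 || k > 31) stop("k must be in 1..31");
  KmerMap m;
  count_into(seqs, k, canonical, m);
  std::vector<uint64_t> keys;
  keys.reserve(m.size());
  for (auto &kv : m) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());  // numeric order == lexicographic order
  CharacterVector kmers(keys.size());
  NumericVector counts(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = decode_kmer(keys[i], k);
    counts[i] = m[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Histogram of k-mer multiplicities without materialising the key strings.
// [[Rcpp::export(name = ".cpp_kmer_histogram")]]
List cpp_kmer_histogram(CharacterVector seqs, int k, bool canonical) {
  if (k <= 0 || k > 31) stop("k must be in 1..31");
  KmerMap m;
  count_into(seqs, k, canonical, m);
  std::unordered_map<double, double> h;
  double total = 0.0;
  for (auto &kv : m) { h[kv.second] += 1.0; total += kv.second; }
  std::vector<double> mult;
  mult.reserve(h.size());
  for (auto &kv : h) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  NumericVector mv(mult.size()), nv(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    mv[i] = mult[i];
    nv[i] = h[mult[i]];
  }
  return List::create(_["multiplicity"] = mv, _["n_kmers"] = nv,
                      _["total_kmers"] = total);
}

// Greedy k-mer extension.  Seeds are processed in descending count order
// (ties: lexicographically smaller k-mer first).  A seed already consumed by
// an earlier extension is skipped but still counts toward `top_n`.  In each
// direction the highest-count overlapping k-mer present in the table is
// chosen (ties: lexicographically smallest appended base); if that k-mer has
// already been used the walk stops there.
// [[Rcpp::export(name = ".cpp_kmer_extend")]]
List cpp_kmer_extend(CharacterVector kmers, NumericVector counts, int k,
                     int top_n, int min_total_len) {
  if (k <= 1 || k > 31) stop("k must be in 2..31");
  R_xlen_t n = kmers.size();
  std::vector<uint64_t> keys(n);
  KmerMap tab;
  tab.reserve((size_t)n * 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t x;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)), k, x))
      stop("k-mer table contains a non-ACGT key");
    keys[i] = x;
    tab[x] = counts[i];
  }
  std::unordered_set<uint64_t> used;
  // seed order: count desc, key asc
  std::vector<R_xlen_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (counts[a] != counts[b]) return counts[a] > counts[b];
    return keys[a] < keys[b];
  });
  const uint64_t sufmask = (1ULL << (2 * (k - 1))) - 1ULL;
  std::vector<std::string> out_seq, out_seed, stop_right, stop_left;
  std::vector<double> out_count;
  int processed = 0;
  for (R_xlen_t oi = 0; oi < n && processed < top_n; ++oi) {
    uint64_t seed = keys[ord[oi]];
    ++processed;
    if (used.count(seed)) continue;  // eliminated by a previous extension
    used.insert(seed);
    std::string seq = decode_kmer(seed, k);
    std::string why_r = "exhausted", why_l = "exhausted";
    // rightward
    uint64_t cur = seed;
    for (;;) {
      uint64_t suf = cur & sufmask;
      double best_c = -1.0;
      uint64_t best = 0;
      bool found = false;
      for (uint64_t b = 0; b < 4; ++b) {
        uint64_t cand = (suf << 2) | b;
        auto it = tab.find(cand);
        if (it != tab.end() && it->second > best_c) {
          best_c = it->second; best = cand; found = true;
        }
      }
      if (!found) break;
      if (used.count(best)) { why_r = "reused"; break; }
      used.insert(best);
      seq.push_back(BITS2BASE[best & 3ULL]);
      cur = best;
    }
    // leftward from the seed's left end
    cur = seed;
    for (;;) {
      uint64_t pre = cur >> 2;
      double best_c = -1.0;
      uint64_t best = 0;
      bool found = false;
      for (uint64_t b = 0; b < 4; ++b) {
        uint64_t cand = (b << (2 * (k - 1))) | pre;
        auto it = tab.find(cand);
        if (it != tab.end() && it->second > best_c) {
          best_c = it->second; best = cand; found = true;
        }
      }
      if (!found) break;
      if (used.count(best)) { why_l = "reused"; break; }
      used.insert(best);
      seq.insert(seq.begin(), BITS2BASE[(best >> (2 * (k - 1))) & 3ULL]);
      cur = best;
    }
    if ((int)seq.size() >= min_total_len) {
      out_seq.push_back(seq);
      out_seed.push_back(decode_kmer(seed, k));
      out_count.push_back(tab[seed]);
      stop_right.push_back(why_r);
      stop_left.push_back(why_l);
    }
  }
  return List::create(_["sequence"] = wrap(out_seq),
                      _["seed"] = wrap(out_seed),
                      _["seed_count"] = wrap(out_count),
                      _["stop_right"] = wrap(stop_right),
                      _["stop_left"] = wrap(stop_left));
}

// For each query k-mer: its own table count plus the summed count over its
// edit-distance-<=1 neighbourhood restricted to length-k strings
// (substitutions; a 1 bp insertion truncated back to k; a 1 bp deletion with
// one free base appended).  Neighbourhoods are deduplicated; when canonical,
// lookups and dedup happen on canonical keys.
// [[Rcpp::export(name = ".cpp_neighbour_counts")]]
List cpp_neighbour_counts(CharacterVector query, CharacterVector kmers,
                          NumericVector counts, int k, bool canonical) {
  KmerMap tab;
  tab.reserve((size_t)kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t x;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)), k, x))
      stop("k-mer table contains a non-ACGT key");
    if (canonical) {
      uint64_t rc = revcomp_packed(x, k);
      if (rc < x) x = rc;
    }
    tab[x] += counts[i];
  }
  auto canon = [&](uint64_t x) {
    if (!canonical) return x;
    uint64_t rc = revcomp_packed(x, k);
    return rc < x ? rc : x;
  };
  R_xlen_t nq = query.size();
  NumericVector own(nq), nb(nq);
  for (R_xlen_t qi = 0; qi < nq; ++qi) {
    const char *qs = CHAR(STRING_ELT(query, qi));
    uint64_t q;
    if (!encode_kmer(qs, k, q)) stop("query k-mer contains a non-ACGT base");
    std::vector<int> bits(k);
    for (int i = 0; i < k; ++i) bits[i] = base2bit(qs[i]);
    std::unordered_set<uint64_t> hood;
    hood.insert(canon(q));
    // a neighbour that is a one-base shift of the query (prefix k-1 equals
    // the query suffix, or vice versa) is indistinguishable from the
    // adjacent window of the same sequence: skip it.  Indels inside
    // homopolymer runs reaching the k-mer edge produce exactly these.
    const uint64_t sufmask = (1ULL << (2 * (k - 1))) - 1ULL;
    auto is_shift = [&](uint64_t x) {
      return (x >> 2) == (q & sufmask) || (x & sufmask) == (q >> 2);
    };
    // substitutions
    for (int i = 0; i < k; ++i) {
      int shift = 2 * (k - 1 - i);
      uint64_t cleared = q & ~(3ULL << shift);
      for (uint64_t b = 0; b < 4; ++b)
        hood.insert(canon(cleared | (b << shift)));
    }
    // insertion of b strictly inside the k-mer, keep first k bases.
    // Boundary insertions/deletions (i = 0) are excluded: they reproduce the
    // adjacent one-base-shifted window of the same sequence and are therefore
    // indistinguishable from no edit at all.
    for (int i = 1; i < k; ++i) {
      for (int b = 0; b < 4; ++b) {
        uint64_t x = 0;
        for (int j = 0; j < i; ++j) x = (x << 2) | (uint64_t)bits[j];
        x = (x << 2) | (uint64_t)b;
        for (int j = i; j < k - 1; ++j) x = (x << 2) | (uint64_t)bits[j];
        if (!is_shift(x)) hood.insert(canon(x));
      }
    }
    // deletion of an internal position i, append free base b
    for (int i = 1; i < k; ++i) {
      for (int b = 0; b < 4; ++b) {
        uint64_t x = 0;
        for (int j = 0; j < k; ++j) {
          if (j == i) continue;
          x = (x << 2) | (uint64_t)bits[j];
        }
        x = (x << 2) | (uint64_t)b;
        if (!is_shift(x)) hood.insert(canon(x));
      }
    }
    double so = 0.0, sn = 0.0;
    auto it0 = tab.find(canon(q));
    if (it0 != tab.end()) so = it0->second;
    for (uint64_t h : hood) {
      auto it = tab.find(h);
      if (it != tab.end()) sn += it->second;
    }
    own[qi] = so;
    nb[qi] = sn;
  }
  return List::create(_["count"] = own, _["neighbourhood_count"] = nb);
}
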