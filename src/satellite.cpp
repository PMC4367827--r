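// Satellite 12-mer co-occurrence scanning over raw reads.
//
// For every read containing the anchor tiling k-mer (allowing up to
// max_mismatch substitutions, on either strand), the read is put into
// anchor-forward frame and the signed offsets of all other tiling k-mer
// occurrences (same orientation or reverse complemented = "flipped") are
// accumulated.
#include <Rcpp.h>
#include <map>
#include <tuple>
#include <vector>
#include <string>
using namespace Rcpp;

static inline char scomp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string srevcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = scomp(c);
  return r;
}

static inline int mismatches(const std::string &s, int pos,
                             const std::string &pat, int maxmm) {
  int mm = 0;
  for (size_t i = 0; i < pat.size(); ++i) {
    if (s[pos + i] != pat[i] && ++mm > maxmm) return mm;
  }
  return mm;
}

// first position of pat in s with <= maxmm mismatches, or -1
static int find_approx(const std::string &s, const std::string &pat,
                       int maxmm) {
  int n = (int)s.size(), k = (int)pat.size();
  for (int p = 0; p + k <= n; ++p)
    if (mismatches(s, p, pat, maxmm) <= maxmm) return p;
  return -1;
}

// [[Rcpp::export(name = ".cpp_satellite_scan")]]
List cpp_satellite_scan(CharacterVector reads, CharacterVector tiling,
                        int max_mismatch) {
  int nt = tiling.size();
  if (nt < 1) stop("need at least one tiling k-mer");
  std::vector<std::string> tf(nt), tr(nt);
  for (int j = 0; j < nt; ++j) {
    tf[j] = as<std::string>(tiling[j]);
    tr[j] = srevcomp(tf[j]);
  }
  const std::string &anchor = tf[0];
  int k = (int)anchor.size();
  // (kmer index, offset, flipped) -> count
  std::map<std::tuple<int, int, int>, int> acc;
  long anchor_reads = 0, total_cooc = 0;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    if ((int)rd.size() < k) continue;
    int ap = find_approx(rd, anchor, max_mismatch);
    std::string frame;
    if (ap >= 0) {
      frame = rd;
    } else {
      std::string rc = srevcomp(rd);
      ap = find_approx(rc, anchor, max_mismatch);
      if (ap < 0) continue;
      frame = rc;
    }
    ++anchor_reads;
    int n = (int)frame.size();
    for (int j = 0; j < nt; ++j) {
      for (int p = 0; p + k <= n; ++p) {
        if (j == 0 && p == ap) continue;  // the anchor occurrence itself
        if (mismatches(frame, p, tf[j], max_mismatch) <= max_mismatch) {
          acc[std::make_tuple(j, p - ap, 0)]++;
          ++total_cooc;
        } else if (mismatches(frame, p, tr[j], max_mismatch) <= max_mismatch) {
          acc[std::make_tuple(j, p - ap, 1)]++;
          ++total_cooc;
        }
      }
    }
  }
  int n = (int)acc.size();
  IntegerVector kk(n), off(n), flip(n), cnt(n);
  int i = 0;
  for (auto &kv : acc) {
    kk[i] = std::get<0>(kv.first) + 1;
    off[i] = std::get<1>(kv.first);
    flip[i] = std::get<2>(kv.first);
    cnt[i] = kv.second;
    ++i;
  }
  return List::create(
      _["table"] = DataFrame::create(_["kmer"] = kk, _["offset"] = off,
                                     _["flipped"] = flip, _["count"] = cnt),
      _["anchor_reads"] = (double)anchor_reads,
      _["cooccurrences"] = (double)total_cooc);
}
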