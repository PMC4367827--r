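// Local similarity search (seed + ungapped X-drop extension) used for
// repeat-library occurrence finding and align-and-extend matching.  Matches
// are substitution-aware only; the synthetic divergences this package is
// exercised on are substitution-dominated, and gapped placement of whole
// reads is handled by the read mapper instead.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int hb2b(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char hcomp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string hrevcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = hcomp(c);
  return r;
}

struct Hit {
  int qstart, qend, rstart, rend;  // 0-based half-open, query coords in the
  double identity;                 // orientation searched
};

// Extend a seed ungapped in both directions with X-drop, then trim to the
// maximum-score extent.  Returns identity over the final extent.
static Hit extend_seed(const std::string &q, const std::string &r, int qp,
                       int rp, int seed_len, int xdrop) {
  int ql = (int)q.size(), rl = (int)r.size();
  // right
  int best_sc = 0, sc = 0, best_i = 0;
  int i = 0;
  while (qp + seed_len + i < ql && rp + seed_len + i < rl) {
    sc += (q[qp + seed_len + i] == r[rp + seed_len + i]) ? 1 : -2;
    ++i;
    if (sc > best_sc) { best_sc = sc; best_i = i; }
    if (best_sc - sc > xdrop) break;
  }
  int right = best_i;
  // left
  best_sc = 0; sc = 0; best_i = 0; i = 0;
  while (qp - 1 - i >= 0 && rp - 1 - i >= 0) {
    sc += (q[qp - 1 - i] == r[rp - 1 - i]) ? 1 : -2;
    ++i;
    if (sc > best_sc) { best_sc = sc; best_i = i; }
    if (best_sc - sc > xdrop) break;
  }
  int left = best_i;
  Hit h;
  h.qstart = qp - left;
  h.qend = qp + seed_len + right;
  h.rstart = rp - left;
  h.rend = rp + seed_len + right;
  int match = 0, len = h.qend - h.qstart;
  for (int j = 0; j < len; ++j)
    if (q[h.qstart + j] == r[h.rstart + j]) ++match;
  h.identity = len > 0 ? (double)match / len : 0.0;
  return h;
}

// [[Rcpp::export(name = ".cpp_find_hits")]]
DataFrame cpp_find_hits(CharacterVector refSeqs, CharacterVector querySeqs,
                        int seed_len, int min_len, double min_id,
                        int max_occ) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in 4..31");
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1ULL;
  // index reference seeds
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > idx;
  std::vector<std::string> refs;
  for (R_xlen_t r = 0; r < refSeqs.size(); ++r) {
    std::string s = as<std::string>(refSeqs[r]);
    refs.push_back(s);
    uint64_t x = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = hb2b(s[i]);
      if (b < 0) { run = 0; x = 0; continue; }
      x = ((x << 2) | (uint64_t)b) & mask;
      if (++run >= seed_len) {
        auto &v = idx[x];
        if ((int)v.size() < max_occ)
          v.push_back(std::make_pair((int)r, i - seed_len + 1));
      }
    }
  }
  std::vector<int> o_q, o_r, o_qs, o_qe, o_rs, o_re, o_strand;
  std::vector<double> o_id;
  for (R_xlen_t qi = 0; qi < querySeqs.size(); ++qi) {
    std::string qf = as<std::string>(querySeqs[qi]);
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? qf : hrevcomp(qf);
      if ((int)q.size() < seed_len) continue;
      // per (rid, diag): covered query intervals already reported
      std::map<std::pair<int, int>, std::vector<std::pair<int, int> > > done;
      uint64_t x = 0;
      int run = 0;
      for (int i = 0; i < (int)q.size(); ++i) {
        int b = hb2b(q[i]);
        if (b < 0) { run = 0; x = 0; continue; }
        x = ((x << 2) | (uint64_t)b) & mask;
        if (run + 1 < seed_len) { ++run; continue; }
        ++run;
        int qp = i - seed_len + 1;
        auto it = idx.find(x);
        if (it == idx.end()) continue;
        for (auto &hp : it->second) {
          int rid = hp.first, rp = hp.second;
          int diag = rp - qp;
          auto key = std::make_pair(rid, diag);
          bool covered = false;
          auto dit = done.find(key);
          if (dit != done.end()) {
            for (auto &iv : dit->second)
              if (qp >= iv.first && qp + seed_len <= iv.second) {
                covered = true;
                break;
              }
          }
          if (covered) continue;
          Hit h = extend_seed(q, refs[rid], qp, rp, seed_len, 20);
          done[key].push_back(std::make_pair(h.qstart, h.qend));
          if (h.qend - h.qstart >= min_len && h.identity >= min_id) {
            int qs = h.qstart, qe = h.qend;
            if (strand == 1) {  // report query coords on the forward query
              qs = (int)qf.size() - h.qend;
              qe = (int)qf.size() - h.qstart;
            }
            o_q.push_back((int)qi + 1);
            o_r.push_back(rid + 1);
            o_qs.push_back(qs);
            o_qe.push_back(qe);
            o_rs.push_back(h.rstart);
            o_re.push_back(h.rend);
            o_strand.push_back(strand == 0 ? 1 : -1);
            o_id.push_back(h.identity);
          }
        }
      }
    }
  }
  return DataFrame::create(_["query"] = o_q, _["rid"] = o_r,
                           _["qstart"] = o_qs, _["qend"] = o_qe,
                           _["rstart"] = o_rs, _["rend"] = o_re,
                           _["strand"] = o_strand, _["identity"] = o_id,
                           _["stringsAsFactors"] = false);
}

// Uniform-coverage read simulation with i.i.d. substitution errors, driven by
// R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".cpp_simulate_reads")]]
List cpp_simulate_reads(std::string genome, int n_frag, int read_len,
                        double error_rate, bool paired, double insert_mean,
                        double insert_sd) {
  RNGScope scope;
  int L = (int)genome.size();
  if (L < read_len) stop("sequence shorter than the read length");
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  auto mutate = [&](std::string &s) {
    if (error_rate <= 0) return;
    for (auto &c : s) {
      if (unif_rand() < error_rate) {
        char n;
        do {
          n = BASES[(int)(unif_rand() * 4) & 3];
        } while (n == c);
        c = n;
      }
    }
  };
  auto rcs = [](const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r)
      switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      }
    return r;
  };
  if (!paired) {
    CharacterVector reads(n_frag);
    IntegerVector pos(n_frag), strand(n_frag);
    for (int i = 0; i < n_frag; ++i) {
      int p = (int)(unif_rand() * (L - read_len + 1));
      if (p > L - read_len) p = L - read_len;
      std::string s = genome.substr(p, read_len);
      bool fwd = unif_rand() < 0.5;
      if (!fwd) s = rcs(s);
      mutate(s);
      reads[i] = s;
      pos[i] = p;
      strand[i] = fwd ? 1 : -1;
    }
    return List::create(_["read1"] = reads, _["pos"] = pos,
                        _["strand"] = strand);
  }
  CharacterVector r1(n_frag), r2(n_frag);
  IntegerVector pos(n_frag), flen(n_frag), strand(n_frag);
  for (int i = 0; i < n_frag; ++i) {
    int fl = (int)(::Rf_rnorm(insert_mean, insert_sd) + 0.5);
    if (fl < read_len) fl = read_len;
    if (fl > L) fl = L;
    int p = (int)(unif_rand() * (L - fl + 1));
    if (p > L - fl) p = L - fl;
    std::string frag = genome.substr(p, fl);
    bool fwd = unif_rand() < 0.5;
    if (!fwd) frag = rcs(frag);
    std::string a = frag.substr(0, read_len);
    std::string b = rcs(frag.substr(fl - read_len, read_len));
    mutate(a);
    mutate(b);
    r1[i] = a;
    r2[i] = b;
    pos[i] = p;
    flen[i] = fl;
    strand[i] = fwd ? 1 : -1;
  }
  return List::create(_["read1"] = r1, _["read2"] = r2, _["pos"] = pos,
                      _["fragment_len"] = flen, _["strand"] = strand);
}
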