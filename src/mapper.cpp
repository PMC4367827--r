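// Lightweight seed-and-extend read mapper and pileup builder.
//
// Contract: each reported alignment is anchored by at least one exact seed
// (default 19 bp), extended to the best-scoring placement of the whole read
// (match +1, mismatch -1, gap open -3, gap extend -1).  A unique best
// placement earns mapq 60; an exact score tie earns 0; otherwise
// min(60, 3 * (best - second)).  Leftmost placement breaks exact ties
// deterministically.  CIGAR uses M/I/D; NM = mismatches + inserted +
// deleted bases.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <tuple>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int b2b(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

struct SeedHit { int32_t rid; int32_t pos; };

struct SeedIndex {
  int seed_len;
  int max_occ;
  std::unordered_map<uint64_t, std::vector<SeedHit> > idx;
  std::vector<std::string> refs;

  void build(const CharacterVector &refSeqs, int sl, int mocc) {
    seed_len = sl;
    max_occ = mocc;
    refs.clear();
    idx.clear();
    const uint64_t mask = (1ULL << (2 * sl)) - 1ULL;
    for (R_xlen_t r = 0; r < refSeqs.size(); ++r) {
      std::string s = as<std::string>(refSeqs[r]);
      refs.push_back(s);
      uint64_t x = 0;
      int run = 0;
      for (int i = 0; i < (int)s.size(); ++i) {
        int b = b2b(s[i]);
        if (b < 0) { run = 0; x = 0; continue; }
        x = ((x << 2) | (uint64_t)b) & mask;
        if (++run >= sl) {
          auto &v = idx[x];
          if ((int)v.size() < max_occ)
            v.push_back(SeedHit{(int32_t)r, (int32_t)(i - sl + 1)});
        }
      }
    }
  }
};

struct Aln {
  int rid = -1;
  int pos = 0;           // 0-based reference start
  int score = INT32_MIN;
  int nm = 0;
  bool fwd = true;
  std::string cigar;
};

// Trim alignment ends so each terminates in `anchor` consecutive matches;
// everything outside becomes a soft clip.  Without clipping, the short
// overhang of a read spanning a reference deletion aligns as a mismatch
// tail *into* the deleted interval and destroys its zero-coverage signal.
// Returns false if no anchored segment exists (alignment rejected).
static bool trim_alignment(const std::string &ref, const std::string &read,
                           Aln &a, int anchor) {
  struct Col { char op; int rp; int qp; bool match; };
  std::vector<Col> cols;
  int rp = a.pos, qp = 0, num = 0;
  for (const char *p = a.cigar.c_str(); *p; ++p) {
    char c = *p;
    if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
    for (int j = 0; j < num; ++j) {
      if (c == 'M' || c == 'X' || c == '=') {
        cols.push_back(Col{'M', rp, qp, ref[rp] == read[qp]});
        ++rp; ++qp;
      } else if (c == 'D') {
        cols.push_back(Col{'D', rp, qp, false});
        ++rp;
      } else if (c == 'I') {
        cols.push_back(Col{'I', rp, qp, false});
        ++qp;
      } else if (c == 'S') {
        ++qp;
      }
    }
    num = 0;
  }
  int n = (int)cols.size();
  auto anchored = [&](int i) {
    if (i + anchor > n) return false;
    for (int j = 0; j < anchor; ++j)
      if (!(cols[i + j].op == 'M' && cols[i + j].match)) return false;
    return true;
  };
  int lo = 0;
  while (lo < n && !anchored(lo)) ++lo;
  if (lo >= n) return false;
  int hi = n - anchor;
  while (hi >= lo && !anchored(hi)) --hi;
  hi += anchor - 1;  // last column retained
  // rebuild cigar with leading/trailing soft clips
  int leadS = cols[lo].qp;
  int tailS = (int)read.size() - (cols[hi].qp + (cols[hi].op != 'D' ? 1 : 0));
  std::string cg;
  auto emit = [&cg](char op, int cnt) {
    if (cnt > 0) cg += std::to_string(cnt) + op;
  };
  emit('S', leadS);
  int score = 0, nm = 0;
  char cur = 0; int cnt = 0;
  bool ingap = false;
  for (int i = lo; i <= hi; ++i) {
    char op = cols[i].op;
    if (op == 'M') {
      score += cols[i].match ? 1 : -1;
      if (!cols[i].match) ++nm;
      ingap = false;
    } else {
      score -= ingap ? 1 : 3;
      ingap = true;
      ++nm;
    }
    if (op == cur) ++cnt;
    else { emit(cur, cnt); cur = op; cnt = 1; }
  }
  emit(cur, cnt);
  emit('S', tailS);
  a.pos = cols[lo].rp;
  a.cigar = cg;
  a.nm = nm;
  a.score = score;
  return true;
}

// Ungapped score of read placed at ref[pos..]; returns INT32_MIN if the
// placement does not fit inside the reference.
static int ungapped(const std::string &ref, const std::string &read, int pos,
                    int &mism) {
  int n = (int)read.size();
  if (pos < 0 || pos + n > (int)ref.size()) return INT32_MIN;
  int mm = 0;
  for (int i = 0; i < n; ++i)
    if (ref[pos + i] != read[i]) ++mm;
  mism = mm;
  return n - 2 * mm;
}

// Semi-global affine alignment: reference window free at both ends, read
// ends soft-clippable at a flat penalty (CLIP).  Clipping makes the optimal
// placement of a deletion-spanning read either the gapped path or a clean
// clip ending at the junction, instead of a mismatch tail bleeding into the
// deleted interval.  Returns score; fills cigar (with S ops), ref start
// offset within window, and NM.
static int dp_align(const std::string &win, const std::string &read,
                    std::string &cigar, int &ref_off, int &nm) {
  const int GO = 3, GE = 1, CLIP = 4;
  int m = (int)read.size(), n = (int)win.size();
  const int NEG = -100000000;
  // M[i][j]: best score aligning read[0..i) to win[0..j) ending in match;
  // X: ending in gap-in-read (deletion from reference consumed);
  // Y: ending in gap-in-ref (insertion of read bases).
  std::vector<int> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  std::vector<int8_t> Bm((m + 1) * (n + 1), 0), Bx((m + 1) * (n + 1), 0),
      By((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0;  // free ref prefix
  // first gap base costs GO, each further base GE (total open 3, extend 1:
  // a g-base gap costs 3 + (g-1)*1)
  for (int i = 1; i <= m; ++i) {
    Y[at(i, 0)] = -(GO + (i - 1) * GE);
    By[at(i, 0)] = (i == 1) ? 1 : 2;  // from M / extend
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (read[i - 1] == win[j - 1]) ? 1 : -1;
      int bm = M[at(i - 1, j - 1)], bx = X[at(i - 1, j - 1)],
          by = Y[at(i - 1, j - 1)];
      int best = bm; int8_t wh = 0;
      if (bx > best) { best = bx; wh = 1; }
      if (by > best) { best = by; wh = 2; }
      if (i > 1 && -CLIP > best) { best = -CLIP; wh = 3; }  // leading clip
      M[at(i, j)] = best + s;
      Bm[at(i, j)] = wh;
      // X: consume win[j-1] with a gap in the read (D)
      int xo = M[at(i, j - 1)] - GO, xe = X[at(i, j - 1)] - GE;
      if (xo >= xe) { X[at(i, j)] = xo; Bx[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; Bx[at(i, j)] = 1; }
      // Y: consume read[i-1] with a gap in the ref (I)
      int yo = M[at(i - 1, j)] - GO, ye = Y[at(i - 1, j)] - GE;
      if (yo >= ye) { Y[at(i, j)] = yo; By[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; By[at(i, j)] = 1; }
    }
  }
  // best end: either the full read (last row) or a trailing clip at any
  // earlier read position, flat CLIP penalty.  Leftmost j wins ties;
  // unclipped beats clipped on equal score.
  int best = NEG, bi = -1, bj = -1;
  for (int j = 0; j <= n; ++j) {
    int v = M[at(m, j)];
    if (v > best) { best = v; bi = m; bj = j; }
  }
  // clipped endpoints win ties against gap-riddled full-read paths, and the
  // longest aligned prefix wins among tied clips
  for (int i = 1; i < m; ++i) {
    for (int j = 0; j <= n; ++j) {
      int v = M[at(i, j)] - CLIP;
      if (v >= best) { best = v; bi = i; bj = j; }
    }
  }
  if (bj < 0) return NEG;
  // traceback
  std::vector<std::pair<char, int> > ops;  // reversed
  int i = bi, j = bj; int8_t st = 0;
  int mism = 0, insb = 0, delb = 0;
  auto push = [&ops](char op, int cnt = 1) {
    if (!ops.empty() && ops.back().first == op) ops.back().second += cnt;
    else ops.push_back(std::make_pair(op, cnt));
  };
  if (bi < m) push('S', m - bi);
  while (i > 0) {
    if (st == 0) {  // M
      if (read[i - 1] != win[j - 1]) ++mism;
      int8_t wh = Bm[at(i, j)];
      push('M');
      --i; --j;
      if (wh == 3) {  // leading clip: remaining read prefix is soft-clipped
        push('S', i);
        i = 0;
        break;
      }
      st = wh;
    } else if (st == 1) {  // X (D)
      int8_t wh = Bx[at(i, j)];
      push('D');
      ++delb;
      --j;
      st = (wh == 0) ? 0 : 1;
    } else {  // Y (I)
      int8_t wh = By[at(i, j)];
      push('I');
      ++insb;
      --i;
      st = (wh == 0) ? 0 : 2;
    }
  }
  ref_off = j;
  nm = mism + insb + delb;
  // strip leading/trailing deletions (reference-only ops outside the read)
  std::reverse(ops.begin(), ops.end());
  while (!ops.empty() && ops.front().first == 'D') {
    ref_off += ops.front().second;
    nm -= ops.front().second;
    best += 3 + ops.front().second - 1;
    ops.erase(ops.begin());
  }
  while (!ops.empty() && ops.back().first == 'D') {
    nm -= ops.back().second;
    best += 3 + ops.back().second - 1;
    ops.pop_back();
  }
  std::string cg;
  for (auto &op : ops) cg += std::to_string(op.second) + op.first;
  cigar = cg;
  return best;
}

// Map reads against references.  Returns one primary alignment per mapped
// read.  gap_pad bounds the largest reference deletion spanned by one read.
// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector refSeqs, CharacterVector readSeqs,
                        int seed_len, int max_occ, int max_cand,
                        int gap_trigger_mm, int gap_pad, int min_score_frac100) {
  SeedIndex ix;
  ix.build(refSeqs, seed_len, max_occ);
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1ULL;

  std::vector<int> o_read, o_rid, o_pos, o_mapq, o_nm, o_score;
  std::vector<std::string> o_cigar;
  std::vector<int> o_strand;  // 1 fwd, -1 rev

  for (R_xlen_t q = 0; q < readSeqs.size(); ++q) {
    std::string fwd = as<std::string>(readSeqs[q]);
    int rlen = (int)fwd.size();
    if (rlen < seed_len) continue;  // unmapped: shorter than seed
    std::string rev = revcomp(fwd);
    // candidate placements: (strand, rid, diag) -> votes
    std::map<std::tuple<int, int, int>, int> votes;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = strand == 0 ? fwd : rev;
      std::vector<int> offs;
      for (int o = 0; o + seed_len <= rlen; o += seed_len) offs.push_back(o);
      if (offs.empty() || offs.back() != rlen - seed_len)
        offs.push_back(rlen - seed_len);
      for (int o : offs) {
        uint64_t x = 0;
        bool ok = true;
        for (int i = 0; i < seed_len; ++i) {
          int b = b2b(s[o + i]);
          if (b < 0) { ok = false; break; }
          x = ((x << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        auto it = ix.idx.find(x);
        if (it == ix.idx.end()) continue;
        for (const SeedHit &h : it->second)
          votes[std::make_tuple(strand, (int)h.rid, (int)h.pos - o)]++;
      }
    }
    if (votes.empty()) continue;
    // order candidates by votes desc then (strand, rid, diag) for determinism
    std::vector<std::pair<int, std::tuple<int, int, int> > > cand;
    for (auto &kv : votes) cand.push_back(std::make_pair(kv.second, kv.first));
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<int, std::tuple<int, int, int> > &a,
                 const std::pair<int, std::tuple<int, int, int> > &b) {
                if (a.first != b.first) return a.first > b.first;
                return a.second < b.second;
              });
    if ((int)cand.size() > max_cand) cand.resize(max_cand);

    std::vector<Aln> evald;
    auto consider = [&](const Aln &a) {
      for (auto &e : evald)
        if (e.rid == a.rid && e.pos == a.pos && e.fwd == a.fwd) {
          if (a.score > e.score) e = a;  // gapped refinement of same spot
          return;
        }
      evald.push_back(a);
    };

    // group candidate diagonals per (strand, rid) to build DP windows that
    // can span a reference deletion (two diagonals differing by the gap)
    for (auto &c : cand) {
      int strand = std::get<0>(c.second);
      int rid = std::get<1>(c.second);
      int diag = std::get<2>(c.second);
      const std::string &s = strand == 0 ? fwd : rev;
      const std::string &ref = ix.refs[rid];
      int mm = 0;
      int sc = ungapped(ref, s, diag, mm);
      if (sc != INT32_MIN && mm <= gap_trigger_mm) {
        Aln a;
        a.rid = rid; a.pos = diag; a.score = sc; a.nm = mm;
        a.fwd = (strand == 0);
        a.cigar = std::to_string(rlen) + "M";
        if (trim_alignment(ref, s, a, 10)) consider(a);
        continue;
      }
      // gapped attempt around this diagonal
      int wstart = std::max(0, diag - 8);
      int wend = std::min((int)ref.size(), diag + rlen + gap_pad);
      if (wend - wstart < rlen / 2) continue;
      std::string win = ref.substr(wstart, wend - wstart);
      std::string cg;
      int roff = 0, nm = 0;
      int dsc = dp_align(win, s, cg, roff, nm);
      if (dsc <= INT32_MIN / 2) continue;
      Aln a;
      a.rid = rid; a.pos = wstart + roff; a.score = dsc; a.nm = nm;
      a.fwd = (strand == 0); a.cigar = cg;
      if (trim_alignment(ref, s, a, 10)) consider(a);
    }
    if (evald.empty()) continue;
    // best: score desc; ties broken by leftmost (rid, pos), forward first
    std::sort(evald.begin(), evald.end(), [](const Aln &a, const Aln &b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.rid != b.rid) return a.rid < b.rid;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.fwd && !b.fwd;
    });
    Aln best = evald[0];
    int min_score = (rlen * min_score_frac100) / 100;
    if (best.score < min_score) continue;
    // mapq measures uniqueness across *loci*: alternative placements within
    // one gap window of the best (e.g. the clipped half vs the gapped path
    // of a deletion-spanning read) describe the same locus, not a repeat.
    int second = INT32_MIN;
    for (size_t e = 1; e < evald.size(); ++e) {
      bool same_locus = evald[e].rid == best.rid &&
        std::abs(evald[e].pos - best.pos) <= rlen + gap_pad;
      if (!same_locus && evald[e].score > second) second = evald[e].score;
    }
    int mapq;
    if (second == INT32_MIN) mapq = 60;
    else if (second >= best.score) mapq = 0;
    else mapq = std::min(60, 3 * (best.score - second));
    o_read.push_back((int)q + 1);
    o_rid.push_back(best.rid + 1);
    o_pos.push_back(best.pos);
    o_strand.push_back(best.fwd ? 1 : -1);
    o_cigar.push_back(best.cigar);
    o_mapq.push_back(mapq);
    o_nm.push_back(best.nm);
    o_score.push_back(best.score);
  }
  return DataFrame::create(_["read"] = o_read, _["rid"] = o_rid,
                           _["pos"] = o_pos, _["strand"] = o_strand,
                           _["cigar"] = o_cigar, _["mapq"] = o_mapq,
                           _["nm"] = o_nm, _["score"] = o_score,
                           _["stringsAsFactors"] = false);
}

// Pileup from alignments.  Deletion ops contribute no base (the site's depth
// excludes that read); deletion and insertion evidence are tracked per site.
// Reads on the reverse strand were already reverse-complemented by the
// mapper's caller convention: `seq` is the read in reference orientation.
// [[Rcpp::export(name = ".cpp_pileup")]]
List cpp_pileup(IntegerVector rid, IntegerVector pos, CharacterVector cigar,
                CharacterVector seq, IntegerVector mapq, int min_q,
                IntegerVector reflens) {
  int nref = reflens.size();
  std::vector<IntegerMatrix> counts;
  std::vector<IntegerVector> delv, insv, inslen;
  for (int r = 0; r < nref; ++r) {
    counts.push_back(IntegerMatrix(4, reflens[r]));
    delv.push_back(IntegerVector(reflens[r]));
    insv.push_back(IntegerVector(reflens[r]));
    inslen.push_back(IntegerVector(reflens[r]));
  }
  R_xlen_t n = rid.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mapq[i] <= min_q) continue;
    int r = rid[i] - 1;
    if (r < 0 || r >= nref) stop("alignment rid out of range");
    int rp = pos[i];
    const char *cg = CHAR(STRING_ELT(cigar, i));
    const char *sq = CHAR(STRING_ELT(seq, i));
    int qp = 0;
    int L = reflens[r];
    int num = 0;
    for (const char *p = cg; *p; ++p) {
      char c = *p;
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
      if (c == 'M' || c == 'X' || c == '=') {
        for (int j = 0; j < num; ++j) {
          if (rp >= 0 && rp < L) {
            int b = b2b(sq[qp]);
            if (b >= 0) counts[r](b, rp)++;
          }
          ++rp; ++qp;
        }
      } else if (c == 'D') {
        for (int j = 0; j < num; ++j) {
          if (rp >= 0 && rp < L) delv[r][rp]++;
          ++rp;
        }
      } else if (c == 'I') {
        if (rp >= 0 && rp < L) { insv[r][rp]++; inslen[r][rp] += num; }
        qp += num;
      } else if (c == 'S') {
        qp += num;
      } else {
        stop("unsupported CIGAR op '%s'", std::string(1, c).c_str());
      }
      num = 0;
    }
  }
  List out(nref);
  for (int r = 0; r < nref; ++r) {
    IntegerVector depth(reflens[r]);
    for (int j = 0; j < reflens[r]; ++j) {
      int d = 0;
      for (int b = 0; b < 4; ++b) d += counts[r](b, j);
      depth[j] = d;
    }
    out[r] = List::create(_["depth"] = depth, _["counts"] = counts[r],
                          _["del"] = delv[r], _["ins"] = insv[r],
                          _["ins_len"] = inslen[r]);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
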