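// Alignment, seeding and read-mapping kernel.
//
// All alignments are scored with linear gap penalties (defaults match=1,
// mismatch=-1, gap=-2).  Identity is matches / alignment columns
// (gap-inclusive).  Non-ACGT characters never match anything, including
// themselves.  Tie-break during DP fill: diagonal > gap-in-b (consume a/read)
// > gap-in-a (consume b/target), which realises the documented
// match > mismatch > gap-in-b > gap-in-a traceback preference (a diagonal
// move is match or mismatch by the characters alone, so the two never
// compete at one cell).

#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) alignment, optionally banded on the offset j - i.
// band < 0 -> full matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b,
                      double match, double mismatch, double gap, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("empty sequence in global alignment");
  int dlo, dhi;
  if (band < 0) { dlo = -m; dhi = n; }
  else {
    const int dend = n - m;
    dlo = std::min(0, dend) - band;
    dhi = std::max(0, dend) + band;
    if (dlo < -m) dlo = -m;
    if (dhi > n)  dhi = n;
  }
  const int W = dhi - dlo + 1;
  const double NEG = -1e18;
  std::vector<double> S((size_t)(m + 1) * W, NEG);
  std::vector<int> M((size_t)(m + 1) * W, 0);   // matches on the chosen path
  std::vector<signed char> P((size_t)(m + 1) * W, 0);
  auto IDX = [&](int i, int j) { return (size_t)i * W + (j - i - dlo); };
  auto INB = [&](int i, int j) {
    const int o = j - i;
    return j >= 0 && j <= n && o >= dlo && o <= dhi;
  };
  S[IDX(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) {
    if (!INB(0, j)) break;
    S[IDX(0, j)] = j * gap; P[IDX(0, j)] = 3;
  }
  // objective is lexicographic (score, matches): maximising matches among
  // co-optimal paths makes the reported identity canonical and symmetric
  for (int i = 1; i <= m; ++i) {
    const int jmin = std::max(0, i + dlo), jmax = std::min(n, i + dhi);
    const int ea = enc_base(a[i - 1]);
    for (int j = jmin; j <= jmax; ++j) {
      double best = NEG; int bm = -1; signed char ptr = 0;
      auto consider = [&](double s, int mm, signed char p) {
        if (s > best || (s == best && mm > bm)) { best = s; bm = mm; ptr = p; }
      };
      if (j >= 1 && INB(i - 1, j - 1)) {
        const double s0 = S[IDX(i - 1, j - 1)];
        if (s0 > NEG / 2) {
          const int eb = enc_base(b[j - 1]);
          const bool hit = (ea >= 0 && ea == eb);
          consider(s0 + (hit ? match : mismatch),
                   M[IDX(i - 1, j - 1)] + (hit ? 1 : 0), 1);
        }
      }
      if (INB(i - 1, j)) {               // gap in b, consume a[i-1]
        const double s0 = S[IDX(i - 1, j)];
        if (s0 > NEG / 2) consider(s0 + gap, M[IDX(i - 1, j)], 2);
      }
      if (j >= 1 && INB(i, j - 1)) {     // gap in a, consume b[j-1]
        const double s0 = S[IDX(i, j - 1)];
        if (s0 > NEG / 2) consider(s0 + gap, M[IDX(i, j - 1)], 3);
      }
      S[IDX(i, j)] = best; M[IDX(i, j)] = bm < 0 ? 0 : bm;
      P[IDX(i, j)] = ptr;
    }
  }
  if (S[IDX(m, n)] <= NEG / 2) stop("band too narrow for global alignment");
  int i = m, j = n, nmat = 0, nmis = 0, nind = 0;
  while (i > 0 || j > 0) {
    const signed char p = P[IDX(i, j)];
    if (p == 1) {
      const int ea = enc_base(a[i - 1]), eb = enc_base(b[j - 1]);
      if (ea >= 0 && ea == eb) ++nmat; else ++nmis;
      --i; --j;
    } else if (p == 2) { ++nind; --i; }
    else { ++nind; --j; }
  }
  return List::create(_["score"] = S[IDX(m, n)], _["matches"] = nmat,
                      _["mismatches"] = nmis, _["indels"] = nind);
}

// ---------------------------------------------------------------------------
// Glocal ("fitting") alignment: the read is consumed end-to-end against the
// best-scoring window of the target; target prefix/suffix are free.  The
// total number of indel columns is bounded by maxindel via a gap-count DP
// state, so the result is the optimal alignment among those with <= maxindel
// indel columns inside the given offset band (j - i in [dlo, dhi]).
// ---------------------------------------------------------------------------

struct GlocalResult {
  bool found;
  double score;
  int matches, mismatches, indels, tstart, tend;
};

static GlocalResult glocal_core(const std::string& r, const std::string& t,
                                double match, double mismatch, double gap,
                                int maxindel, int dlo, int dhi,
                                std::vector<double>* counts4, double weight) {
  GlocalResult res; res.found = false; res.score = 0;
  res.matches = res.mismatches = res.indels = res.tstart = res.tend = 0;
  const int m = (int)r.size(), n = (int)t.size();
  if (m == 0 || n == 0) return res;
  const int G = maxindel < 0 ? 0 : maxindel;
  if (dlo < -G) dlo = -G;                 // start offset >= 0, drift <= G
  if (dhi > n) dhi = n;
  if (dhi < dlo) return res;
  const int W = dhi - dlo + 1, GS = G + 1;
  const double NEG = -1e18;
  std::vector<double> S((size_t)(m + 1) * W * GS, NEG);
  std::vector<signed char> P((size_t)(m + 1) * W * GS, 0);
  auto IDX = [&](int i, int j, int g) {
    return ((size_t)i * W + (j - i - dlo)) * GS + g;
  };
  auto INB = [&](int i, int j) {
    const int o = j - i;
    return j >= 0 && j <= n && o >= dlo && o <= dhi;
  };
  {
    const int jmin = std::max(0, dlo), jmax = std::min(n, dhi);
    for (int j = jmin; j <= jmax; ++j) S[IDX(0, j, 0)] = 0.0;  // free start
  }
  for (int i = 1; i <= m; ++i) {
    const int jmin = std::max(0, i + dlo), jmax = std::min(n, i + dhi);
    const int er = enc_base(r[i - 1]);
    for (int j = jmin; j <= jmax; ++j) {
      for (int g = 0; g < GS; ++g) {
        double best = NEG; signed char ptr = 0;
        if (j >= 1 && INB(i - 1, j - 1)) {
          const double s0 = S[IDX(i - 1, j - 1, g)];
          if (s0 > NEG / 2) {
            const int et = enc_base(t[j - 1]);
            const double s = s0 + ((er >= 0 && er == et) ? match : mismatch);
            if (s > best) { best = s; ptr = 1; }
          }
        }
        if (g >= 1 && INB(i - 1, j)) {    // gap in target, consume read base
          const double s0 = S[IDX(i - 1, j, g - 1)];
          if (s0 > NEG / 2 && s0 + gap > best) { best = s0 + gap; ptr = 2; }
        }
        if (g >= 1 && j >= 1 && INB(i, j - 1)) {  // gap in read
          const double s0 = S[IDX(i, j - 1, g - 1)];
          if (s0 > NEG / 2 && s0 + gap > best) { best = s0 + gap; ptr = 3; }
        }
        S[IDX(i, j, g)] = best; P[IDX(i, j, g)] = ptr;
      }
    }
  }
  // pick best end cell; scan ascending j then g, replace on strictly greater
  double best = NEG; int bj = -1, bg = -1;
  {
    const int jmin = std::max(0, m + dlo), jmax = std::min(n, m + dhi);
    for (int j = jmin; j <= jmax; ++j)
      for (int g = 0; g < GS; ++g)
        if (S[IDX(m, j, g)] > best) { best = S[IDX(m, j, g)]; bj = j; bg = g; }
  }
  if (bj < 0 || best <= NEG / 2) return res;
  int i = m, j = bj, g = bg, nmat = 0, nmis = 0, nind = 0;
  while (i > 0) {
    const signed char p = P[IDX(i, j, g)];
    if (p == 0) break;                    // reached a free-start cell
    if (p == 1) {
      const int er = enc_base(r[i - 1]), et = enc_base(t[j - 1]);
      if (er >= 0 && er == et) ++nmat; else ++nmis;
      if (counts4 && er >= 0) (*counts4)[(size_t)er * t.size() + (j - 1)] += weight;
      --i; --j;
    } else if (p == 2) { ++nind; --g; --i; }
    else { ++nind; --g; --j; }
  }
  res.found = true; res.score = best;
  res.matches = nmat; res.mismatches = nmis; res.indels = nind;
  res.tstart = j; res.tend = bj;
  return res;
}

// [[Rcpp::export]]
List cpp_align_glocal(std::string read, std::string target,
                      double match, double mismatch, double gap, int maxindel) {
  const int m = (int)read.size(), n = (int)target.size();
  GlocalResult r = glocal_core(read, target, match, mismatch, gap, maxindel,
                               -maxindel, (n - m) + 2 * maxindel, nullptr, 0.0);
  return List::create(_["found"] = r.found, _["score"] = r.score,
                      _["matches"] = r.matches, _["mismatches"] = r.mismatches,
                      _["indels"] = r.indels, _["tstart"] = r.tstart,
                      _["tend"] = r.tend);
}

// ---------------------------------------------------------------------------
// k-mer index + seeded mapping
// ---------------------------------------------------------------------------

// Exact fitting alignment for maxindel <= 1 via per-diagonal match prefix
// sums: the optimal alignment is either ungapped on one diagonal, or a
// prefix on diagonal d joined to a suffix on d+1 (one target base skipped,
// a deletion in the read) or on d-1 (one read base unaligned, an
// insertion).  O(L * #diagonals) instead of a DP, and exact because a
// single indel column is exactly one diagonal switch.

struct FitCand {
  bool found;
  double score;
  int matches, mismatches, indels, tstart, tend;
};

class DiagPrefix {
  // lazily computed match-prefix sums per diagonal
  const std::string& s;
  const std::string& t;
  std::vector<int> diags;
  std::deque<std::vector<int>> pref;  // deque: stable references on growth
public:
  DiagPrefix(const std::string& s_, const std::string& t_) : s(s_), t(t_) {}
  // valid iff the read fits fully inside the target on this diagonal
  bool valid(int d) const {
    return d >= 0 && d + (int)s.size() <= (int)t.size();
  }
  const std::vector<int>& get(int d) {
    for (size_t i = 0; i < diags.size(); ++i)
      if (diags[i] == d) return pref[i];
    const int L = (int)s.size();
    std::vector<int> p(L + 1, 0);
    for (int i = 0; i < L; ++i) {
      const int es = enc_base(s[i]), et = enc_base(t[d + i]);
      p[i + 1] = p[i] + (es >= 0 && es == et ? 1 : 0);
    }
    diags.push_back(d);
    pref.push_back(std::move(p));
    return pref.back();
  }
};

static FitCand fit1_best(const std::string& s, const std::string& t,
                         int dmin, int dmax, int G) {
  FitCand best; best.found = false; best.score = -1e18;
  best.matches = best.mismatches = best.indels = best.tstart = best.tend = 0;
  const int L = (int)s.size();
  DiagPrefix dp(s, t);
  const int lo = dmin - G, hi = dmax + G;
  auto consider = [&](double score, int m, int mm, int g, int ts, int te) {
    if (!best.found || score > best.score) {
      best.found = true; best.score = score; best.matches = m;
      best.mismatches = mm; best.indels = g; best.tstart = ts;
      best.tend = te;
    }
  };
  for (int d = lo; d <= hi; ++d) {
    if (!dp.valid(d)) continue;
    const int m = dp.get(d)[L];
    consider(2.0 * m - L, m, L - m, 0, d, d + L);
  }
  if (G >= 1) {
    for (int d = lo; d <= hi; ++d) {
      // deletion in read: prefix on d, suffix on d+1, one target base skipped
      if (dp.valid(d) && dp.valid(d + 1)) {
        const std::vector<int>& a = dp.get(d);
        const std::vector<int>& b = dp.get(d + 1);
        int bestp = -1, bestm = -1;
        for (int p = 1; p <= L - 1; ++p) {
          const int m = a[p] + (b[L] - b[p]);
          if (m > bestm) { bestm = m; bestp = p; }
        }
        if (bestp >= 0)
          consider(2.0 * bestm - L - 2, bestm, L - bestm, 1, d, d + 1 + L);
      }
      // insertion in read: read base p unaligned; prefix on d, suffix on d-1
      if (dp.valid(d - 1) && (d >= 0)) {
        const std::vector<int>& b = dp.get(d - 1);
        int bestp = -1, bestm = -1;
        if (!dp.valid(d)) {
          // only p = 0 possible (empty prefix)
          const int m = b[L] - b[1];
          bestm = m; bestp = 0;
        } else {
          const std::vector<int>& a = dp.get(d);
          for (int p = 0; p <= L - 1; ++p) {
            const int m = a[p] + (b[L] - b[p + 1]);
            if (m > bestm) { bestm = m; bestp = p; }
          }
        }
        if (bestp >= 0)
          consider(2.0 * bestm - L - 1, bestm, L - 1 - bestm, 1,
                   bestp > 0 ? d : d - 1 + 1, d - 1 + L);
      }
    }
  }
  return best;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> KmerIndex;

static void index_targets(const std::vector<std::string>& tgt, int k,
                          KmerIndex& index) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int ti = 0; ti < (int)tgt.size(); ++ti) {
    const std::string& s = tgt[ti];
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      const int e = enc_base(s[p]);
      if (e < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)e) & mask;
      if (++run >= k) index[key].push_back(std::make_pair(ti, p - k + 1));
    }
  }
}

// collect (diag, rpos) seed hits of `s` per target; returns touched targets
// and the number of valid (N-free) k-mers in the read
static int seed_hits(const std::string& s, int k, const KmerIndex& index,
                     std::vector<std::vector<std::pair<int, int>>>& bucket,
                     std::vector<int>& touched) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t key = 0; int run = 0, valid = 0;
  for (int p = 0; p < (int)s.size(); ++p) {
    const int e = enc_base(s[p]);
    if (e < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    if (++run < k) continue;
    ++valid;
    KmerIndex::const_iterator it = index.find(key);
    if (it == index.end()) continue;
    const int rp = p - k + 1;
    for (size_t h = 0; h < it->second.size(); ++h) {
      const int ti = it->second[h].first, tp = it->second[h].second;
      if (bucket[ti].empty()) touched.push_back(ti);
      bucket[ti].push_back(std::make_pair(tp - rp, rp));
    }
  }
  return valid;
}

// best diagonal window (span <= 2*maxindel) by seed count; returns the
// count and the window [dmin,dmax].  Counting is per diagonal (a read
// position hitting two window diagonals counts twice, a harmless
// overcount for a prefilter); targets produce only a handful of distinct
// diagonals per read, so linear insertion beats sorting the seed list.
static int best_window(std::vector<std::pair<int, int>>& hits, int maxindel,
                       int& dmin_out, int& dmax_out) {
  std::vector<std::pair<int, int>> dc;   // (diag, count)
  dc.reserve(4);
  for (size_t h = 0; h < hits.size(); ++h) {
    const int d = hits[h].first;
    bool found = false;
    for (size_t x = 0; x < dc.size(); ++x)
      if (dc[x].first == d) { ++dc[x].second; found = true; break; }
    if (!found) dc.push_back(std::make_pair(d, 1));
  }
  std::sort(dc.begin(), dc.end());
  const int span = 2 * maxindel;
  int best = 0;
  size_t lo = 0;
  for (size_t hi = 0; hi < dc.size(); ++hi) {
    while (dc[hi].first - dc[lo].first > span) ++lo;
    int total = 0;
    for (size_t q = lo; q <= hi; ++q) total += dc[q].second;
    if (total > best) {
      best = total;
      dmin_out = dc[lo].first; dmax_out = dc[hi].first;
    }
  }
  return best;
}

// Seeded read mapping.  mode 0: emit every hit with identity >= minid
// (one best row per read x target).  mode 1: emit only the best-score tie
// rows of reads whose best identity reaches idfilter (the mapped/unmapped
// decision), which is what the read mapper consumes.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector targets,
                        int k, int minhits, int maxindel, double minid,
                        double match, double mismatch, double gap,
                        bool both_strands, int mode, double idfilter) {
  const int nt = (int)targets.size();
  std::vector<std::string> tgt(nt);
  for (int i = 0; i < nt; ++i) tgt[i] = as<std::string>(targets[i]);
  KmerIndex index;
  index_targets(tgt, k, index);

  std::vector<int> out_q, out_t, out_mat, out_mis, out_ind, out_ts, out_te;
  std::vector<double> out_sc, out_id;
  std::vector<int> out_strand;  // 1 = '+', -1 = '-'

  std::vector<std::vector<std::pair<int, int>>> bucket(nt);
  std::vector<int> touched;
  // per-read accumulator: best hit per target across strands/windows
  struct Row {
    int target, strand, mat, mis, ind, ts, te;
    double score, id;
  };
  std::vector<Row> acc;
  std::vector<int> seen(nt, -1);
  std::vector<size_t> rowof(nt, 0);

  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    const std::string fwd = as<std::string>(reads[ri]);
    acc.clear();
    // a candidate with identity >= minid destroys at most k k-mers per
    // edit, so it must share at least valid - k*e_allow seed positions;
    // skipping candidates below that bound never changes the output
    const int L = (int)fwd.size();
    const int e_allow = (minid > 0)
        ? (int)std::floor((1.0 - minid) * (L + maxindel)) : L;
    for (int str = 0; str < (both_strands ? 2 : 1); ++str) {
      const std::string s = (str == 0) ? fwd : revcomp_str(fwd);
      touched.clear();
      const int valid = seed_hits(s, k, index, bucket, touched);
      int need = minhits;
      const long long bound = (long long)valid - (long long)k * e_allow;
      if (bound > need) need = (int)bound;
      for (size_t x = 0; x < touched.size(); ++x) {
        const int ti = touched[x];
        int dmin = 0, dmax = 0;
        const int cnt = best_window(bucket[ti], maxindel, dmin, dmax);
        bucket[ti].clear();
        if (cnt < need) continue;
        double score; int mat, mis, ind, ts, te;
        if (maxindel <= 1) {
          FitCand f = fit1_best(s, tgt[ti], dmin, dmax, maxindel);
          if (!f.found) continue;
          score = f.score; mat = f.matches; mis = f.mismatches;
          ind = f.indels; ts = f.tstart; te = f.tend;
        } else {
          GlocalResult g = glocal_core(s, tgt[ti], match, mismatch, gap,
                                       maxindel, dmin - maxindel - 1,
                                       dmax + maxindel + 1, nullptr, 0.0);
          if (!g.found) continue;
          score = g.score; mat = g.matches; mis = g.mismatches;
          ind = g.indels; ts = g.tstart; te = g.tend;
        }
        const int cols = mat + mis + ind;
        const double id = cols > 0 ? (double)mat / cols : 0.0;
        if (id < minid) continue;
        const int strand = (str == 0) ? 1 : -1;
        if (seen[ti] == (int)ri) {
          Row& r = acc[rowof[ti]];      // keep better score; tie -> '+'
          if (score > r.score || (score == r.score && strand > r.strand)) {
            r.score = score; r.id = id; r.mat = mat; r.mis = mis;
            r.ind = ind; r.ts = ts; r.te = te; r.strand = strand;
          }
        } else {
          seen[ti] = (int)ri; rowof[ti] = acc.size();
          Row r; r.target = ti; r.strand = strand; r.mat = mat; r.mis = mis;
          r.ind = ind; r.ts = ts; r.te = te; r.score = score; r.id = id;
          acc.push_back(r);
        }
      }
    }
    if (acc.empty()) continue;
    size_t lo = 0, hi = acc.size();
    if (mode == 1) {
      double bs = -1e18;
      for (size_t x = 0; x < acc.size(); ++x)
        if (acc[x].score > bs) bs = acc[x].score;
      double bid = -1.0;
      for (size_t x = 0; x < acc.size(); ++x)
        if (acc[x].score == bs && acc[x].id > bid) bid = acc[x].id;
      if (bid < idfilter) continue;     // unit is unmapped
      size_t w = 0;
      for (size_t x = 0; x < acc.size(); ++x)
        if (acc[x].score == bs) acc[w++] = acc[x];
      hi = w;
    }
    for (size_t x = lo; x < hi; ++x) {
      const Row& r = acc[x];
      out_q.push_back((int)ri + 1); out_t.push_back(r.target + 1);
      out_sc.push_back(r.score); out_id.push_back(r.id);
      out_mat.push_back(r.mat); out_mis.push_back(r.mis);
      out_ind.push_back(r.ind); out_ts.push_back(r.ts);
      out_te.push_back(r.te); out_strand.push_back(r.strand);
    }
  }
  return DataFrame::create(
      _["query"] = out_q, _["target"] = out_t, _["strand"] = out_strand,
      _["score"] = out_sc, _["identity"] = out_id, _["matches"] = out_mat,
      _["mismatches"] = out_mis, _["indels"] = out_ind,
      _["tstart"] = out_ts, _["tend"] = out_te,
      _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_seed_candidates(std::string read, CharacterVector targets,
                                  int k, int minhits, int maxindel,
                                  bool both_strands) {
  const int nt = (int)targets.size();
  std::vector<std::string> tgt(nt);
  for (int i = 0; i < nt; ++i) tgt[i] = as<std::string>(targets[i]);
  KmerIndex index;
  index_targets(tgt, k, index);
  std::vector<std::vector<std::pair<int, int>>> bucket(nt);
  std::vector<int> touched;
  std::vector<bool> pass(nt, false);
  for (int str = 0; str < (both_strands ? 2 : 1); ++str) {
    const std::string s = (str == 0) ? read : revcomp_str(read);
    touched.clear();
    seed_hits(s, k, index, bucket, touched);
    for (size_t x = 0; x < touched.size(); ++x) {
      const int ti = touched[x];
      int dmin = 0, dmax = 0;
      if (best_window(bucket[ti], maxindel, dmin, dmax) >= minhits)
        pass[ti] = true;
      bucket[ti].clear();
    }
  }
  std::vector<int> out;
  for (int i = 0; i < nt; ++i) if (pass[i]) out.push_back(i + 1);
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Posterior-weighted base counts for EM consensus.  Reads are already
// oriented to the target's '+' strand; tstart/indels come from the most
// recent alignment against this very target sequence.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_consensus_counts(std::string target, CharacterVector reads,
                                   IntegerVector tstart, IntegerVector indels,
                                   NumericVector w, int maxindel,
                                   double match, double mismatch, double gap) {
  const int n = (int)target.size();
  std::vector<double> counts((size_t)4 * n, 0.0);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const std::string r = as<std::string>(reads[i]);
    const double wt = w[i];
    if (wt <= 0) continue;
    if (indels[i] == 0 && tstart[i] >= 0 && tstart[i] + (int)r.size() <= n) {
      const int t0 = tstart[i];
      for (int p = 0; p < (int)r.size(); ++p) {
        const int e = enc_base(r[p]);
        if (e >= 0) counts[(size_t)e * n + (t0 + p)] += wt;
      }
    } else {
      glocal_core(r, target, match, mismatch, gap, maxindel,
                  tstart[i] - maxindel - 1, tstart[i] + maxindel + 1,
                  &counts, wt);
    }
  }
  NumericMatrix out(4, n);
  for (int b = 0; b < 4; ++b)
    for (int j = 0; j < n; ++j) out(b, j) = counts[(size_t)b * n + j];
  return out;
}

// ---------------------------------------------------------------------------
// Overlap merging of read pairs (BBMerge-style stand-in).  An overlap of ov
// bases means: the last ov bases of seq1 pair with the first ov bases of
// revcomp(seq2).  Best-scoring qualifying overlap wins; score = matches -
// mismatches; ties prefer the longer overlap.  Overlap bases are resolved by
// the higher quality score, ties keep the seq1 base.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector seq2,
                     CharacterVector qual1, CharacterVector qual2,
                     int min_overlap, double max_mismatch_rate) {
  const R_xlen_t np = seq1.size();
  CharacterVector mseq(np), mqual(np);
  LogicalVector merged(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    const std::string s1 = as<std::string>(seq1[i]);
    const std::string q1 = as<std::string>(qual1[i]);
    const std::string rc2 = revcomp_str(as<std::string>(seq2[i]));
    std::string rq2 = as<std::string>(qual2[i]);
    std::reverse(rq2.begin(), rq2.end());
    const int l1 = (int)s1.size(), l2 = (int)rc2.size();
    const int ovmax = std::min(l1, l2);
    int best_ov = -1; double best_score = -1e18;
    for (int ov = min_overlap; ov <= ovmax; ++ov) {
      int mis = 0, mat = 0;
      const int allowed = (int)(max_mismatch_rate * ov);
      bool ok = true;
      for (int p = 0; p < ov; ++p) {
        const int e1 = enc_base(s1[l1 - ov + p]), e2 = enc_base(rc2[p]);
        if (e1 >= 0 && e1 == e2) ++mat;
        else if (++mis > allowed) { ok = false; break; }
      }
      if (!ok) continue;
      const double sc = (double)mat - (double)mis;
      if (sc > best_score || (sc == best_score && ov > best_ov)) {
        best_score = sc; best_ov = ov;
      }
    }
    if (best_ov < 0) {
      merged[i] = false; mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      continue;
    }
    const int ov = best_ov;
    std::string ms = s1.substr(0, l1 - ov);
    std::string mq = q1.substr(0, l1 - ov);
    for (int p = 0; p < ov; ++p) {
      const char c1 = s1[l1 - ov + p], c2 = rc2[p];
      const char x1 = q1[l1 - ov + p], x2 = rq2[p];
      if (c1 == c2) { ms.push_back(c1); mq.push_back(std::max(x1, x2)); }
      else if (x2 > x1) { ms.push_back(c2); mq.push_back(x2); }
      else { ms.push_back(c1); mq.push_back(x1); }
    }
    ms += rc2.substr(ov);
    mq += rq2.substr(ov);
    merged[i] = true; mseq[i] = ms; mqual[i] = mq;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq, _["qual"] = mqual);
}

// ---------------------------------------------------------------------------
// Shared distinct-k-mer fraction (relative to the smaller k-mer set) for all
// sequence pairs -- a conservative prefilter before banded global alignment:
// one substitution/indel destroys at most k k-mers, so identity >= 1 - d
// implies a shared fraction >= 1 - ~k*d.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_shared_kmer_frac(CharacterVector seqs, int k) {
  const int ns = (int)seqs.size();
  std::vector<std::vector<uint64_t>> sets(ns);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int i = 0; i < ns; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    uint64_t key = 0, rkey = 0; int run = 0;
    std::vector<uint64_t>& v = sets[i];
    for (int p = 0; p < (int)s.size(); ++p) {
      const int e = enc_base(s[p]);
      if (e < 0) { run = 0; key = 0; rkey = 0; continue; }
      key = ((key << 2) | (uint64_t)e) & mask;
      rkey = (rkey >> 2) | ((uint64_t)(3 - e) << (2 * (k - 1)));
      // canonical (strand-min) k-mers so reverse-complement near-duplicates
      // pass the prefilter; the both-strand aligner then decides
      if (++run >= k) v.push_back(std::min(key, rkey & mask));
    }
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  NumericMatrix out(ns, ns);
  for (int i = 0; i < ns; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < ns; ++j) {
      const std::vector<uint64_t>& A = sets[i];
      const std::vector<uint64_t>& B = sets[j];
      size_t a = 0, b = 0, inter = 0;
      while (a < A.size() && b < B.size()) {
        if (A[a] == B[b]) { ++inter; ++a; ++b; }
        else if (A[a] < B[b]) ++a;
        else ++b;
      }
      const size_t mn = std::min(A.size(), B.size());
      const double f = mn > 0 ? (double)inter / (double)mn : 0.0;
      out(i, j) = f; out(j, i) = f;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fragment assembly from unit-level mapped tie rows (mode-1 output of
// cpp_map_reads).  A merged unit's fragment hit set is its tie rows; an
// unmerged pair's hit set is the targets present in BOTH mates' tie sets
// with opposite strands.  Returns one fragment row per (pair, target) with
// the tie count k, plus the per-target coverage rows of the contributing
// alignments.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pair_fragments(IntegerVector query, IntegerVector target,
                        IntegerVector strand, IntegerVector tstart,
                        IntegerVector tend, IntegerVector matches,
                        IntegerVector mismatches, IntegerVector unit_pair,
                        IntegerVector unit_mate, int n_pairs) {
  const int n_units = unit_pair.size();
  std::vector<std::vector<int>> rows(n_units);
  for (int r = 0; r < query.size(); ++r)
    rows[query[r] - 1].push_back(r);
  // units of each pair: [merged, mate1, mate2], -1 when absent
  std::vector<std::array<int, 3>> punit(
      (size_t)n_pairs, std::array<int, 3>{{-1, -1, -1}});
  for (int u = 0; u < n_units; ++u)
    punit[unit_pair[u] - 1][unit_mate[u]] = u;

  std::vector<int> f_pair, f_target, f_k;
  std::vector<int> c_target, c_ts, c_te, c_ab;
  auto push_cov = [&](int r) {
    c_target.push_back(target[r]); c_ts.push_back(tstart[r]);
    c_te.push_back(tend[r]); c_ab.push_back(matches[r] + mismatches[r]);
  };
  std::vector<int> ftmp;
  for (int p = 0; p < n_pairs; ++p) {
    ftmp.clear();
    const int u0 = punit[p][0], u1 = punit[p][1], u2 = punit[p][2];
    if (u0 >= 0 && !rows[u0].empty()) {
      for (int r : rows[u0]) { ftmp.push_back(target[r]); push_cov(r); }
    } else if (u1 >= 0 && u2 >= 0 && !rows[u1].empty() &&
               !rows[u2].empty()) {
      for (int r1 : rows[u1]) {
        for (int r2 : rows[u2]) {
          if (target[r1] == target[r2] && strand[r1] != strand[r2]) {
            ftmp.push_back(target[r1]);
            push_cov(r1); push_cov(r2);
            break;                       // one row per (unit, target)
          }
        }
      }
    }
    if (ftmp.empty()) continue;
    std::sort(ftmp.begin(), ftmp.end());
    ftmp.erase(std::unique(ftmp.begin(), ftmp.end()), ftmp.end());
    for (int t : ftmp) {
      f_pair.push_back(p + 1); f_target.push_back(t);
      f_k.push_back((int)ftmp.size());
    }
  }
  return List::create(
      _["pair_idx"] = wrap(f_pair), _["target"] = wrap(f_target),
      _["k"] = wrap(f_k), _["cov_target"] = wrap(c_target),
      _["cov_tstart"] = wrap(c_ts), _["cov_tend"] = wrap(c_te),
      _["cov_albases"] = wrap(c_ab));
}

// ---------------------------------------------------------------------------
// Re-score cached read-candidate alignments after a candidate's consensus
// changed.  Substitution-only consensus updates keep coordinates stable, so
// ungapped hits are re-scanned at their recorded start; hits with indels are
// re-aligned in a small band around it.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_rescore_hits(CharacterVector oriented, CharacterVector targets,
                           IntegerVector tgt_idx, IntegerVector tstart,
                           IntegerVector indels, int maxindel,
                           double match, double mismatch, double gap) {
  const int n = oriented.size();
  std::vector<std::string> tgt(targets.size());
  for (int i = 0; i < (int)targets.size(); ++i)
    tgt[i] = as<std::string>(targets[i]);
  IntegerVector o_mat(n), o_mis(n), o_ind(n), o_ts(n), o_te(n);
  NumericVector o_sc(n), o_id(n);
  for (int i = 0; i < n; ++i) {
    const std::string r = as<std::string>(oriented[i]);
    const std::string& t = tgt[tgt_idx[i] - 1];
    const int L = (int)r.size(), ts = tstart[i];
    if (indels[i] == 0 && ts >= 0 && ts + L <= (int)t.size()) {
      int m = 0;
      for (int p = 0; p < L; ++p) {
        const int er = enc_base(r[p]), et = enc_base(t[ts + p]);
        if (er >= 0 && er == et) ++m;
      }
      o_mat[i] = m; o_mis[i] = L - m; o_ind[i] = 0;
      o_ts[i] = ts; o_te[i] = ts + L;
      o_sc[i] = match * m + mismatch * (L - m);
      o_id[i] = (double)m / L;
    } else {
      GlocalResult g = glocal_core(r, t, match, mismatch, gap, maxindel,
                                   ts - maxindel - 1, ts + maxindel + 1,
                                   nullptr, 0.0);
      if (!g.found) { o_id[i] = 0; o_sc[i] = -1e18; continue; }
      o_mat[i] = g.matches; o_mis[i] = g.mismatches; o_ind[i] = g.indels;
      o_ts[i] = g.tstart; o_te[i] = g.tend; o_sc[i] = g.score;
      const int cols = g.matches + g.mismatches + g.indels;
      o_id[i] = cols > 0 ? (double)g.matches / cols : 0.0;
    }
  }
  return DataFrame::create(_["matches"] = o_mat, _["mismatches"] = o_mis,
                           _["indels"] = o_ind, _["tstart"] = o_ts,
                           _["tend"] = o_te, _["score"] = o_sc,
                           _["identity"] = o_id,
                           _["stringsAsFactors"] = false);
}
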