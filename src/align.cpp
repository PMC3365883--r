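#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Semi-global (free end-gap) pairwise alignment with affine gap costs,
// Gotoh three-state recursion. Terminal overhangs of either sequence are
// unpenalised, so a fragment aligns to its containing region at no cost.
// Scoring: match/mismatch for A,C,G,T pairs; any pair involving an
// ambiguity code scores 0 (such sites are excluded from distance counts
// downstream anyway). Gap of length L costs open + L * extend.
//
// Deterministic tie-breaking: at equal score the diagonal (match) state is
// preferred over a gap in the reference (up) over a gap in the query
// (left), both when filling and when tracing back.

static const double NEG_INF = -1e30;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct AlnCounts {
  int overlap, transitions, transversions, gap_openings;
};

// Core DP. q is the query, r the reference. If build_strings is true the
// gapped aligned strings (overlap region only) are returned.
static void align_core(const std::string& q, const std::string& r,
                       double match, double mismatch,
                       double gap_open, double gap_extend,
                       AlnCounts& counts, bool build_strings,
                       std::string& qa, std::string& ra) {
  const int m = q.size(), n = r.size();
  // state matrices: M diagonal, Y gap-in-ref (consumes query, "up"),
  // X gap-in-query (consumes reference, "left")
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  // traceback: 0 from M, 1 from Y, 2 from X, 3 start
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 3);
  std::vector<unsigned char> tbX((m + 1) * (n + 1), 3);
  std::vector<unsigned char> tbY((m + 1) * (n + 1), 3);
  const double go = -std::abs(gap_open), ge = -std::abs(gap_extend);
  #define IDX(i, j) ((i) * (n + 1) + (j))

  for (int i = 1; i <= m; ++i) {
    const int ci = base_code(q[i - 1]);
    for (int j = 1; j <= n; ++j) {
      const int cj = base_code(r[j - 1]);
      double s = (ci < 0 || cj < 0) ? 0.0
                 : (ci == cj ? match : mismatch);
      // M: predecessors at (i-1, j-1); free start on the border
      double pm = M[IDX(i - 1, j - 1)], py = Y[IDX(i - 1, j - 1)],
             px = X[IDX(i - 1, j - 1)];
      double start = (i == 1 || j == 1) ? 0.0 : NEG_INF;
      double best = pm; unsigned char tb = 0;
      if (py > best) { best = py; tb = 1; }
      if (px > best) { best = px; tb = 2; }
      if (start > best) { best = start; tb = 3; }
      M[IDX(i, j)] = best + s; tbM[IDX(i, j)] = tb;
      // Y: gap in reference, consumes q[i-1], predecessor (i-1, j)
      double yo = M[IDX(i - 1, j)] + go + ge;
      double ye = Y[IDX(i - 1, j)] + ge;
      if (yo >= ye) { Y[IDX(i, j)] = yo; tbY[IDX(i, j)] = 0; }
      else { Y[IDX(i, j)] = ye; tbY[IDX(i, j)] = 1; }
      // X: gap in query, consumes r[j-1], predecessor (i, j-1)
      double xo = M[IDX(i, j - 1)] + go + ge;
      double xe = X[IDX(i, j - 1)] + ge;
      if (xo >= xe) { X[IDX(i, j)] = xo; tbX[IDX(i, j)] = 0; }
      else { X[IDX(i, j)] = xe; tbX[IDX(i, j)] = 2; }
    }
  }

  // end cell: best M over the last row and last column (free trailing
  // overhang); gaps at the very end are never preferred over ending at M
  int bi = m, bj = n; double best = NEG_INF;
  for (int j = n; j >= 1; --j)
    if (M[IDX(m, j)] > best) { best = M[IDX(m, j)]; bi = m; bj = j; }
  for (int i = m; i >= 1; --i)
    if (M[IDX(i, n)] > best) { best = M[IDX(i, n)]; bi = i; bj = n; }

  // traceback from (bi, bj) in state M
  counts.overlap = counts.transitions = counts.transversions = 0;
  counts.gap_openings = 0;
  std::string qrev, rrev;
  int i = bi, j = bj; unsigned char state = 0;
  bool in_gap = false;
  while (i > 0 && j > 0) {
    if (state == 0) {
      const int ci = base_code(q[i - 1]), cj = base_code(r[j - 1]);
      if (build_strings) { qrev.push_back(q[i - 1]); rrev.push_back(r[j - 1]); }
      if (ci >= 0 && cj >= 0) {
        ++counts.overlap;
        if (ci != cj) {
          bool ti = (ci == 0 && cj == 2) || (ci == 2 && cj == 0) ||
                    (ci == 1 && cj == 3) || (ci == 3 && cj == 1);
          if (ti) ++counts.transitions; else ++counts.transversions;
        }
      }
      in_gap = false;
      unsigned char prev = tbM[IDX(i, j)];
      --i; --j;
      if (prev == 3) break;
      state = prev;
    } else if (state == 1) {  // gap in reference
      if (build_strings) { qrev.push_back(q[i - 1]); rrev.push_back('-'); }
      if (!in_gap) { ++counts.gap_openings; in_gap = true; }
      unsigned char prev = tbY[IDX(i, j)];
      --i;
      state = prev;
      if (prev == 0) in_gap = false;
    } else {  // state == 2, gap in query
      if (build_strings) { qrev.push_back('-'); rrev.push_back(r[j - 1]); }
      if (!in_gap) { ++counts.gap_openings; in_gap = true; }
      unsigned char prev = tbX[IDX(i, j)];
      --j;
      state = prev;
      if (prev == 0) in_gap = false;
    }
  }
  if (build_strings) {
    qa.assign(qrev.rbegin(), qrev.rend());
    ra.assign(rrev.rbegin(), rrev.rend());
  }
  #undef IDX
}

// Banded variant of the same recursion, restricted to diagonals
// j - i in [d0 - band, d0 + band]. Exact whenever the optimal alignment
// stays inside the band; callers seed d0 from shared k-mers and fall back
// to the full DP when no seed exists.
static void align_core_banded(const std::string& q, const std::string& r,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              int d0, int band, AlnCounts& counts) {
  const int m = q.size(), n = r.size();
  const int W = 2 * band + 1;           // columns stored per row
  const int dlo = d0 - band;
  std::vector<double> M((m + 1) * W, NEG_INF);
  std::vector<double> X((m + 1) * W, NEG_INF);
  std::vector<double> Y((m + 1) * W, NEG_INF);
  std::vector<unsigned char> tbM((m + 1) * W, 3);
  std::vector<unsigned char> tbX((m + 1) * W, 3);
  std::vector<unsigned char> tbY((m + 1) * W, 3);
  const double go = -std::abs(gap_open), ge = -std::abs(gap_extend);
  // column j maps to offset j - i - dlo within row i
  #define BIDX(i, off) ((i) * W + (off))
  for (int i = 1; i <= m; ++i) {
    const int ci = base_code(q[i - 1]);
    int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dlo + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      const int off = j - i - dlo;
      const int cj = base_code(r[j - 1]);
      double s = (ci < 0 || cj < 0) ? 0.0 : (ci == cj ? match : mismatch);
      // (i-1, j-1) sits at the same offset in the previous row
      double pm = NEG_INF, py = NEG_INF, px = NEG_INF;
      pm = M[BIDX(i - 1, off)]; py = Y[BIDX(i - 1, off)];
      px = X[BIDX(i - 1, off)];
      double start = (i == 1 || j == 1) ? 0.0 : NEG_INF;
      double best = pm; unsigned char tb = 0;
      if (py > best) { best = py; tb = 1; }
      if (px > best) { best = px; tb = 2; }
      if (start > best) { best = start; tb = 3; }
      M[BIDX(i, off)] = best + s; tbM[BIDX(i, off)] = tb;
      // Y consumes q: predecessor (i-1, j) at offset off+1
      double yo = NEG_INF, ye = NEG_INF;
      if (off + 1 < W) {
        yo = M[BIDX(i - 1, off + 1)] + go + ge;
        ye = Y[BIDX(i - 1, off + 1)] + ge;
      }
      if (yo >= ye) { Y[BIDX(i, off)] = yo; tbY[BIDX(i, off)] = 0; }
      else { Y[BIDX(i, off)] = ye; tbY[BIDX(i, off)] = 1; }
      // X consumes r: predecessor (i, j-1) at offset off-1
      double xo = NEG_INF, xe = NEG_INF;
      if (off - 1 >= 0) {
        xo = M[BIDX(i, off - 1)] + go + ge;
        xe = X[BIDX(i, off - 1)] + ge;
      }
      if (xo >= xe) { X[BIDX(i, off)] = xo; tbX[BIDX(i, off)] = 0; }
      else { X[BIDX(i, off)] = xe; tbX[BIDX(i, off)] = 2; }
    }
  }
  // end cell: best M with i == m or j == n inside the band
  int bi = -1, bj = -1; double best = NEG_INF;
  {
    int jlo = std::max(1, m + dlo), jhi = std::min(n, m + dlo + W - 1);
    for (int j = jhi; j >= jlo; --j) {
      double v = M[BIDX(m, j - m - dlo)];
      if (v > best) { best = v; bi = m; bj = j; }
    }
    for (int i = m; i >= 1; --i) {
      int off = n - i - dlo;
      if (off < 0 || off >= W) continue;
      double v = M[BIDX(i, off)];
      if (v > best) { best = v; bi = i; bj = n; }
    }
  }
  counts.overlap = counts.transitions = counts.transversions = 0;
  counts.gap_openings = 0;
  if (bi < 0) return;  // band never touched a valid end cell
  int i = bi, j = bj; unsigned char state = 0; bool in_gap = false;
  while (i > 0 && j > 0) {
    int off = j - i - dlo;
    if (state == 0) {
      const int ci = base_code(q[i - 1]), cj = base_code(r[j - 1]);
      if (ci >= 0 && cj >= 0) {
        ++counts.overlap;
        if (ci != cj) {
          bool ti = (ci == 0 && cj == 2) || (ci == 2 && cj == 0) ||
                    (ci == 1 && cj == 3) || (ci == 3 && cj == 1);
          if (ti) ++counts.transitions; else ++counts.transversions;
        }
      }
      in_gap = false;
      unsigned char prev = tbM[BIDX(i, off)];
      --i; --j;
      if (prev == 3) break;
      state = prev;
    } else if (state == 1) {
      if (!in_gap) { ++counts.gap_openings; in_gap = true; }
      unsigned char prev = tbY[BIDX(i, off)];
      --i; state = prev;
      if (prev == 0) in_gap = false;
    } else {
      if (!in_gap) { ++counts.gap_openings; in_gap = true; }
      unsigned char prev = tbX[BIDX(i, off)];
      --j; state = prev;
      if (prev == 0) in_gap = false;
    }
  }
  #undef BIDX
}

// Most-supported diagonal j - i from shared k-mers (k = 8); returns
// false when query and reference share no clean k-mer.
static bool seed_diagonal(const std::string& q, const std::string& r,
                          int& d0, int& support) {
  const int K = 8;
  const int m = q.size(), n = r.size();
  if (m < K || n < K) return false;
  static std::vector<int> head, nxt, stamp;
  static int epoch = 0;
  const int NH = 1 << (2 * K);
  if ((int)head.size() != NH) { head.assign(NH, -1); stamp.assign(NH, -1); }
  nxt.assign(n, -1);
  ++epoch;
  // index reference k-mers
  int code = 0, valid = 0;
  for (int j = 0; j < n; ++j) {
    int c = base_code(r[j]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | c) & (NH - 1);
    if (++valid < K) continue;
    int pos = j - K + 1;
    if (stamp[code] != epoch) { stamp[code] = epoch; head[code] = pos; }
    else { nxt[pos] = head[code]; head[code] = pos; }
  }
  std::vector<int> votes(m + n + 1, 0);
  code = 0; valid = 0;
  int bestv = 0, bestd = 0;
  for (int i = 0; i < m; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | c) & (NH - 1);
    if (++valid < K) continue;
    if (stamp[code] != epoch) continue;
    int qpos = i - K + 1;
    for (int p = head[code]; p >= 0; p = nxt[p]) {
      int d = p - qpos + m;  // shift to non-negative
      if (++votes[d] > bestv) { bestv = votes[d]; bestd = d - m; }
    }
  }
  if (bestv == 0) return false;
  d0 = bestd;
  support = bestv;
  return true;
}

static const int BAND_DEFAULT = 24;

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string query, std::string ref,
                    double match = 1, double mismatch = -1,
                    double gap_open = 10, double gap_extend = 1) {
  AlnCounts c; std::string qa, ra;
  align_core(query, ref, match, mismatch, gap_open, gap_extend,
             c, true, qa, ra);
  return List::create(_["query_aln"] = qa, _["ref_aln"] = ra,
                      _["overlap_sites"] = c.overlap,
                      _["transitions"] = c.transitions,
                      _["transversions"] = c.transversions,
                      _["internal_gaps"] = c.gap_openings);
}

// Batch comparison of one query against many references. Each pair is
// aligned in a band around the diagonal best supported by shared 8-mers
// (exact whenever the optimal alignment stays within the band, which for
// indel-free barcode fragments is the ungapped diagonal itself); pairs
// with no shared 8-mer, and any pair whose banded alignment finds no end
// cell, fall back to the full dynamic program.
// [[Rcpp::export(name = ".align_counts_cpp")]]
IntegerMatrix align_counts_cpp(std::string query, CharacterVector refs,
                               double match = 1, double mismatch = -1,
                               double gap_open = 10, double gap_extend = 1,
                               int band = 24) {
  const int nr = refs.size();
  IntegerMatrix out(nr, 4);
  colnames(out) = CharacterVector::create("overlap_sites", "transitions",
                                          "transversions", "internal_gaps");
  std::string qa, ra;
  for (int k = 0; k < nr; ++k) {
    std::string r = as<std::string>(refs[k]);
    AlnCounts c;
    int d0 = 0, support = 0;
    bool done = false;
    if (band > 0 && seed_diagonal(query, r, d0, support) && support >= 4) {
      align_core_banded(query, r, match, mismatch, gap_open, gap_extend,
                        d0, band, c);
      // trust the banded result only when it is gapless: a gap (or an
      // empty result) hints that the true alignment left the band
      done = c.overlap > 0 && c.gap_openings == 0;
    }
    if (!done)
      align_core(query, r, match, mismatch, gap_open, gap_extend,
                 c, false, qa, ra);
    out(k, 0) = c.overlap; out(k, 1) = c.transitions;
    out(k, 2) = c.transversions; out(k, 3) = c.gap_openings;
  }
  return out;
}
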