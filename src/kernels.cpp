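#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const double NEG = -1e30;

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// Affine-gap local alignment score (Smith-Waterman), optionally banded.
// a, b: 1-based indices into submat rows/cols. A gap of length L costs
// gap_open + L * gap_ext. band <= 0 runs the full matrix; otherwise cells
// with column offset outside [min(0,n-m)-band, max(0,n-m)+band] are skipped
// (adequate when the two sequences are globally similar).
// [[Rcpp::export(name = ".sw_score")]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                    double gap_open, double gap_ext, int band) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0.0;
  const int lo_off = std::min(0, n - m) - (band > 0 ? band : 0);
  const int hi_off = std::max(0, n - m) + (band > 0 ? band : 0);
  const int A = submat.nrow();
  // flatten for unchecked row-major access
  std::vector<double> sub((size_t)A * A);
  for (int x = 0; x < A; ++x)
    for (int y = 0; y < A; ++y) sub[(size_t)x * A + y] = submat(x, y);
  std::vector<double> M0(n + 2, NEG), X0(n + 2, NEG), Y0(n + 2, NEG);
  std::vector<double> M1(n + 2, NEG), X1(n + 2, NEG), Y1(n + 2, NEG);
  for (int j = 0; j <= n; ++j) M0[j] = 0.0;
  const double go = gap_open + gap_ext;
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (band > 0) {
      jlo = std::max(1, i + lo_off);
      jhi = std::min(n, i + hi_off);
      if (jlo > jhi) continue;
    }
    // the next row only reads positions jlo-1 .. jhi+1; the band edge
    // moves by at most one per row, so clearing the two boundary cells
    // keeps every readable cell defined without touching the full row
    M1[jlo - 1] = 0.0;  // fresh local start
    X1[jlo - 1] = NEG; Y1[jlo - 1] = NEG;
    M1[jhi + 1] = NEG; X1[jhi + 1] = NEG; Y1[jhi + 1] = NEG;
    const double *srow = &sub[(size_t)(a[i - 1] - 1) * A];
    for (int j = jlo; j <= jhi; ++j) {
      const double s = srow[b[j - 1] - 1];
      double diag = max3(M0[j - 1], X0[j - 1], Y0[j - 1]);
      if (diag < 0.0) diag = 0.0;
      M1[j] = diag + s;
      X1[j] = max3(M0[j] - go, X0[j] - gap_ext, Y0[j] - go);
      Y1[j] = max3(M1[j - 1] - go, Y1[j - 1] - gap_ext, X1[j - 1] - go);
      if (M1[j] > best) best = M1[j];
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return best;
}

// Full Smith-Waterman with traceback; returns score, identity counts and
// the aligned span on both sequences.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["nid"] = 0, _["ncol"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  const double go = gap_open + gap_ext;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
      Y((m + 1) * W, NEG);
  // traceback codes: 0 stop (local start), 1 from M, 2 from X, 3 from Y
  std::vector<uint8_t> tM((m + 1) * W, 0), tX((m + 1) * W, 0),
      tY((m + 1) * W, 0);
  for (int j = 0; j <= n; ++j) M[j] = 0.0;
  for (int i = 0; i <= m; ++i) M[i * W] = 0.0;
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int id = i * W + j, up = (i - 1) * W + j, dg = (i - 1) * W + j - 1,
                lf = i * W + j - 1;
      const double s = submat(a[i - 1] - 1, b[j - 1] - 1);
      // M state
      double dM = M[dg], dX = X[dg], dY = Y[dg];
      double dbest = max3(dM, dX, dY);
      uint8_t code = dbest == dM ? 1 : (dbest == dX ? 2 : 3);
      if (dbest < 0.0) { dbest = 0.0; code = 0; }
      M[id] = dbest + s; tM[id] = code;
      // X: gap in b (consume a)
      double x1 = M[up] - go, x2 = X[up] - gap_ext, x3 = Y[up] - go;
      X[id] = max3(x1, x2, x3);
      tX[id] = X[id] == x1 ? 1 : (X[id] == x2 ? 2 : 3);
      // Y: gap in a (consume b)
      double y1 = M[lf] - go, y2 = Y[lf] - gap_ext, y3 = X[lf] - go;
      Y[id] = max3(y1, y2, y3);
      tY[id] = Y[id] == y1 ? 1 : (Y[id] == y2 ? 3 : 2);
      if (M[id] > best) { best = M[id]; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 1, nid = 0, ncol = 0;
  int a_end = bi, b_end = bj;
  while (i > 0 && j > 0) {
    const int id = i * W + j;
    if (state == 1) {
      ++ncol;
      if (a[i - 1] == b[j - 1]) ++nid;
      int code = tM[id];
      --i; --j;
      if (code == 0) break;
      state = code;
    } else if (state == 2) {
      ++ncol; state = tX[id]; --i;
    } else {
      ++ncol; state = tY[id]; --j;
    }
  }
  return List::create(_["score"] = best, _["nid"] = nid, _["ncol"] = ncol,
                      _["a_start"] = i + 1, _["a_end"] = a_end,
                      _["b_start"] = j + 1, _["b_end"] = b_end);
}

// Global (Needleman-Wunsch) affine-gap alignment over a precomputed
// column-vs-column score matrix S (rows = columns of profile A, cols =
// columns of profile B). End gaps are penalized. Returns aligned column
// indices, 0 marking a gap.
// [[Rcpp::export(name = ".nw_profile")]]
List nw_profile_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  const int m = S.nrow(), n = S.ncol();
  const double go = gap_open + gap_ext;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
      Y((m + 1) * W, NEG);
  std::vector<uint8_t> tM((m + 1) * W, 0), tX((m + 1) * W, 0),
      tY((m + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) { X[i * W] = -go - gap_ext * (i - 1); tX[i * W] = 2; }
  for (int j = 1; j <= n; ++j) { Y[j] = -go - gap_ext * (j - 1); tY[j] = 3; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int id = i * W + j, up = (i - 1) * W + j, dg = (i - 1) * W + j - 1,
                lf = i * W + j - 1;
      double dM = M[dg], dX = X[dg], dY = Y[dg];
      double dbest = max3(dM, dX, dY);
      M[id] = dbest + S(i - 1, j - 1);
      tM[id] = dbest == dM ? 1 : (dbest == dX ? 2 : 3);
      double x1 = M[up] - go, x2 = X[up] - gap_ext, x3 = Y[up] - go;
      X[id] = max3(x1, x2, x3);
      tX[id] = X[id] == x1 ? 1 : (X[id] == x2 ? 2 : 3);
      double y1 = M[lf] - go, y2 = Y[lf] - gap_ext, y3 = X[lf] - go;
      Y[id] = max3(y1, y2, y3);
      tY[id] = Y[id] == y1 ? 1 : (Y[id] == y2 ? 3 : 2);
    }
  }
  const int id = m * W + n;
  double fin = max3(M[id], X[id], Y[id]);
  int state = fin == M[id] ? 1 : (fin == X[id] ? 2 : 3);
  std::vector<int> ai, bi;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    const int cid = i * W + j;
    if (state == 1) {
      ai.push_back(i); bi.push_back(j); state = tM[cid]; --i; --j;
    } else if (state == 2) {
      ai.push_back(i); bi.push_back(0); state = tX[cid]; --i;
    } else {
      ai.push_back(0); bi.push_back(j); state = tY[cid]; --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = fin, _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

// Sliding ungapped window scores for a PSSM. S: width x A score matrix
// (columns indexed by residue code 1..A, last column = unknown residue);
// prot: residue codes 1..A. Returns one score per window start.
// [[Rcpp::export(name = ".pssm_scores")]]
NumericVector pssm_scores_cpp(IntegerVector prot, NumericMatrix S) {
  const int L = prot.size(), w = S.nrow();
  if (L < w) return NumericVector(0);
  NumericVector out(L - w + 1);
  for (int o = 0; o < L - w + 1; ++o) {
    double s = 0.0;
    for (int j = 0; j < w; ++j) s += S(j, prot[o + j] - 1);
    out[o] = s;
  }
  return out;
}

// Candidate homolog pairs by shared k-mer counting. kmers: list of sorted
// unique integer k-mer codes per sequence. Codes occurring in more than
// max_group sequences are skipped (low-complexity guard). Returns pairs
// (1-based sequence indices, i < j) sharing >= min_shared distinct codes.
// [[Rcpp::export(name = ".kmer_shared_pairs")]]
DataFrame kmer_shared_pairs_cpp(List kmers, int max_group, int min_shared) {
  const int N = kmers.size();
  std::vector<std::pair<int, int> > ent;  // (code, seq)
  for (int s = 0; s < N; ++s) {
    IntegerVector v = kmers[s];
    for (int t = 0; t < v.size(); ++t) ent.push_back(std::make_pair(v[t], s));
  }
  std::sort(ent.begin(), ent.end());
  std::unordered_map<uint64_t, int> counts;
  size_t g0 = 0;
  for (size_t t = 0; t <= ent.size(); ++t) {
    if (t == ent.size() || ent[t].first != ent[g0].first) {
      const size_t gs = t - g0;
      if (gs >= 2 && gs <= (size_t)max_group) {
        for (size_t p = g0; p < t; ++p)
          for (size_t q = p + 1; q < t; ++q) {
            uint64_t key = ((uint64_t)ent[p].second << 32) |
                           (uint64_t)ent[q].second;
            ++counts[key];
          }
      }
      g0 = t;
    }
  }
  std::vector<int> ii, jj, cc;
  for (std::unordered_map<uint64_t, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it) {
    if (it->second >= min_shared) {
      ii.push_back((int)(it->first >> 32) + 1);
      jj.push_back((int)(it->first & 0xffffffffULL) + 1);
      cc.push_back(it->second);
    }
  }
  return DataFrame::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                           _["shared"] = wrap(cc));
}
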