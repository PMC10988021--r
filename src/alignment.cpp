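#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment over an arbitrary alphabet with a
// substitution matrix. Gap of length L costs open + (L - 1) * ext (the first
// gapped residue is charged the opening penalty, each further residue the
// extension penalty). Traceback is deterministic: at equal scores the
// preference is diagonal > gap-in-reference > gap-in-query, and for local
// alignment the start cell is the highest-scoring cell scanning row-major
// (leftmost-topmost on ties), which yields the leftmost of the longest
// maximal alignments under this preference.

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  std::string aq, ar;
  int qs, qe, rs, re; // 1-based inclusive spans, 0 if empty
};

static AlnResult gotoh(const std::vector<int>& q, const std::vector<int>& r,
                       const NumericMatrix& S, double open, double ext,
                       bool local) {
  const int n = q.size(), m = r.size();
  // DP matrices: M (match), X (gap in reference: consume query), Y (gap in query)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X = M, Y = M;
  // traceback codes per matrix: 0 stop, 1 from M, 2 from X, 3 from Y
  std::vector<std::vector<unsigned char>> tM(n + 1, std::vector<unsigned char>(m + 1, 0));
  std::vector<std::vector<unsigned char>> tX = tM, tY = tM;

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (local) { M[i][0] = 0.0; }
    else {
      X[i][0] = -open - (i - 1) * ext;
      tX[i][0] = (i == 1) ? 1 : 2;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) { M[0][j] = 0.0; }
    else {
      Y[0][j] = -open - (j - 1) * ext;
      tY[0][j] = (j == 1) ? 1 : 3;
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // X: gap in reference (query residue i aligned to '-')
      double xm = M[i - 1][j] - open, xx = X[i - 1][j] - ext;
      if (xm >= xx) { X[i][j] = xm; tX[i][j] = 1; } else { X[i][j] = xx; tX[i][j] = 2; }
      // Y: gap in query
      double ym = M[i][j - 1] - open, yy = Y[i][j - 1] - ext;
      if (ym >= yy) { Y[i][j] = ym; tY[i][j] = 1; } else { Y[i][j] = yy; tY[i][j] = 3; }
      // M: diagonal
      double s = S(q[i - 1], r[j - 1]);
      double dm = M[i - 1][j - 1], dx = X[i - 1][j - 1], dy = Y[i - 1][j - 1];
      double best = dm; unsigned char tb = 1;
      if (dx > best) { best = dx; tb = 2; }
      if (dy > best) { best = dy; tb = 3; }
      double v = best + s;
      if (local && v < 0.0) { v = 0.0; tb = 0; }
      M[i][j] = v; tM[i][j] = tb;
    }
  }

  int bi = n, bj = m; int mat = 1; double sc;
  if (local) {
    sc = 0.0; bi = 0; bj = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M[i][j] > sc) { sc = M[i][j]; bi = i; bj = j; }
    mat = 1;
  } else {
    sc = M[n][m]; mat = 1;
    if (X[n][m] > sc) { sc = X[n][m]; mat = 2; }
    if (Y[n][m] > sc) { sc = Y[n][m]; mat = 3; }
  }

  AlnResult out; out.score = sc;
  std::string moves; // 'D' diagonal, 'X' gap in ref, 'Y' gap in query (reversed)
  int i = bi, j = bj, cm = mat;
  int qe = 0, re = 0;
  while (i > 0 || j > 0) {
    if (cm == 1) {
      if (local && M[i][j] <= 0.0) break;
      if (i == 0 && j == 0) break;
      if (qe == 0) { qe = i; re = j; }
      moves.push_back('D');
      cm = tM[i][j]; --i; --j;
    } else if (cm == 2) {
      if (qe == 0) { qe = i; re = j; }
      moves.push_back('X');
      cm = tX[i][j]; --i;
    } else if (cm == 3) {
      if (qe == 0) { qe = i; re = j; }
      moves.push_back('Y');
      cm = tY[i][j]; --j;
    } else break;
  }
  int qs = i + 1, rs = j + 1;
  // rebuild aligned strings from the move string (reversed)
  std::string mq, mr;
  int qi = qs - 1, rj = rs - 1; // 0-based positions to consume
  for (auto it = moves.rbegin(); it != moves.rend(); ++it) {
    char mv = *it;
    if (mv == 'D') { mq.push_back((char)('A' + q[qi])); mr.push_back((char)('A' + r[rj])); ++qi; ++rj; }
    else if (mv == 'X') { mq.push_back((char)('A' + q[qi])); mr.push_back('-'); ++qi; }
    else { mq.push_back('-'); mr.push_back((char)('A' + r[rj])); ++rj; }
  }
  out.aq = mq; out.ar = mr;
  if (qe == 0) { out.qs = 0; out.qe = 0; out.rs = 0; out.re = 0; }
  else { out.qs = qs; out.qe = qe; out.rs = rs; out.re = re; }
  return out;
}

// [[Rcpp::export]]
List cpp_align(std::string q, std::string r, NumericMatrix sub,
               std::string alphabet, double gap_open, double gap_ext,
               bool local) {
  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k) lut[(unsigned char)alphabet[k]] = k;
  std::vector<int> qi(q.size()), ri(r.size());
  for (size_t k = 0; k < q.size(); ++k) {
    int v = lut[(unsigned char)q[k]];
    if (v < 0) stop("unknown residue '%s' in query at position %d",
                    std::string(1, q[k]).c_str(), (int)k + 1);
    qi[k] = v;
  }
  for (size_t k = 0; k < r.size(); ++k) {
    int v = lut[(unsigned char)r[k]];
    if (v < 0) stop("unknown residue '%s' in reference at position %d",
                    std::string(1, r[k]).c_str(), (int)k + 1);
    ri[k] = v;
  }
  AlnResult a = gotoh(qi, ri, sub, gap_open, gap_ext, local);
  // decode aligned strings back to the alphabet
  std::string aq, ar;
  int n_id = 0, n_pos = 0, r_res = 0, cols = 0;
  for (size_t k = 0; k < a.aq.size(); ++k) {
    char cq = a.aq[k], cr = a.ar[k];
    char dq = (cq == '-') ? '-' : alphabet[cq - 'A'];
    char dr = (cr == '-') ? '-' : alphabet[cr - 'A'];
    aq.push_back(dq); ar.push_back(dr);
    ++cols;
    if (dr != '-') ++r_res;
    if (dq != '-' && dr != '-') {
      if (dq == dr) ++n_id;
      if (sub(lut[(unsigned char)dq], lut[(unsigned char)dr]) > 0) ++n_pos;
    }
  }
  return List::create(
    _["score"] = a.score, _["query_aln"] = aq, _["ref_aln"] = ar,
    _["q_start"] = a.qs, _["q_end"] = a.qe,
    _["r_start"] = a.rs, _["r_end"] = a.re,
    _["n_identical"] = n_id, _["n_positive"] = n_pos,
    _["n_columns"] = cols, _["n_ref_aligned"] = r_res);
}

// Global alignment of two gapped DNA profiles (rows A, C, G, T, '-'; columns
// are frequencies) with linear gap penalty for newly introduced gap columns.
// Column-vs-column score is the expected pairwise score; a residue against a
// pre-existing profile gap scores `gap` weighted by the gap frequency.
// Returns a 2 x L path matrix of source column indices (0 = new gap).
// [[Rcpp::export]]
IntegerMatrix cpp_profile_align(NumericMatrix A, NumericMatrix B,
                                double match, double mismatch, double gap) {
  const int n = A.ncol(), m = B.ncol();
  // flat copies of the profiles (column-major, 5 rows) for fast access
  const double* pA = A.begin();
  const double* pB = B.begin();
  // two-row rolling DP for scores; full (n+1) x (m+1) traceback in bytes
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> T((size_t)(n + 1) * (m + 1), 0);
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) { prev[j] = prev[j - 1] + gap; T[j] = 3; }
  const double dmm = match - mismatch;
  for (int i = 1; i <= n; ++i) {
    unsigned char* Ti = &T[(size_t)i * (m + 1)];
    cur[0] = prev[0] + gap; Ti[0] = 2;
    const double* ai = pA + 5 * (i - 1);
    const double a0 = ai[0], a1 = ai[1], a2 = ai[2], a3 = ai[3], ga = ai[4];
    const double ra = 1.0 - ga;
    for (int j = 1; j <= m; ++j) {
      const double* bj = pB + 5 * (j - 1);
      const double gb = bj[4], rb = 1.0 - gb;
      // expected pairwise score: (match - mismatch) * <fA, fB>
      //   + mismatch * resA * resB + gap cross-terms for existing gaps
      double s = dmm * (a0 * bj[0] + a1 * bj[1] + a2 * bj[2] + a3 * bj[3])
               + mismatch * ra * rb + (ga * rb + gb * ra) * gap;
      double d = prev[j - 1] + s;
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; unsigned char tb = 1;
      if (u > best) { best = u; tb = 2; }
      if (l > best) { best = l; tb = 3; }
      cur[j] = best; Ti[j] = tb;
    }
    std::swap(prev, cur);
  }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char tb = T[(size_t)i * (m + 1) + j];
    if (tb == 1) { pa.push_back(i); pb.push_back(j); --i; --j; }
    else if (tb == 2) { pa.push_back(i); pb.push_back(0); --i; }
    else { pa.push_back(0); pb.push_back(j); --j; }
  }
  int L = pa.size();
  IntegerMatrix path(2, L);
  for (int k = 0; k < L; ++k) {
    path(0, k) = pa[L - 1 - k];
    path(1, k) = pb[L - 1 - k];
  }
  return path;
}
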