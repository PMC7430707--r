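#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap alignment over a precomputed column-score matrix.
//
// S(i, j) is the score of aligning unit i of sequence/profile A with unit j
// of B.  Gap cost convention follows EMBOSS: the first residue of a gap run
// costs `gap_open`, every further residue costs `gap_extend` (both given as
// positive penalties).  `local = true` gives Smith-Waterman, otherwise
// Needleman-Wunsch.  Traceback ties are broken diagonal > up > left, where
// "up" consumes a unit of A against a gap.
//
// Returns list(ai, bi, score): ai/bi are 1-based indices into A and B with
// 0 marking a gap in that row.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(NumericMatrix S, double gap_open, double gap_extend,
                      bool local) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);  // ends in a pair
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);  // ends consuming A
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);  // ends consuming B
  // predecessor state feeding each cell: 0=M, 1=X, 2=Y, -1 = fresh start
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), 0);
  std::vector<signed char> tbY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -gap_open - (i - 1) * gap_extend;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -gap_open - (j - 1) * gap_extend;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: align A[i] with B[j]
      double d0 = M[at(i - 1, j - 1)], d1 = X[at(i - 1, j - 1)],
             d2 = Y[at(i - 1, j - 1)];
      double dbest = d0; signed char dwho = 0;
      if (d1 > dbest) { dbest = d1; dwho = 1; }
      if (d2 > dbest) { dbest = d2; dwho = 2; }
      if (local && dbest < 0.0) { dbest = 0.0; dwho = -1; }
      double mval = (dbest <= NEG_INF / 2) ? NEG_INF : dbest + S(i - 1, j - 1);
      M[at(i, j)] = mval; tbM[at(i, j)] = dwho;
      // X: A[i] against a gap
      double x0 = M[at(i - 1, j)] - gap_open;
      double x1 = X[at(i - 1, j)] - gap_extend;
      double x2 = Y[at(i - 1, j)] - gap_open;
      double xbest = x0; signed char xwho = 0;
      if (x1 > xbest) { xbest = x1; xwho = 1; }
      if (x2 > xbest) { xbest = x2; xwho = 2; }
      X[at(i, j)] = xbest; tbX[at(i, j)] = xwho;
      // Y: B[j] against a gap
      double y0 = M[at(i, j - 1)] - gap_open;
      double y1 = X[at(i, j - 1)] - gap_open;
      double y2 = Y[at(i, j - 1)] - gap_extend;
      double ybest = y0; signed char ywho = 0;
      if (y1 > ybest) { ybest = y1; ywho = 1; }
      if (y2 > ybest) { ybest = y2; ywho = 2; }
      Y[at(i, j)] = ybest; tbY[at(i, j)] = ywho;
      if (local && mval > best) { best = mval; best_i = i; best_j = j; }
    }
  }

  int i, j, state;
  double score;
  if (local) {
    if (best <= 0.0)
      return List::create(_["ai"] = IntegerVector(0),
                          _["bi"] = IntegerVector(0), _["score"] = 0.0);
    i = best_i; j = best_j; state = 0; score = best;
  } else {
    i = n; j = m;
    double e0 = M[at(n, m)], e1 = X[at(n, m)], e2 = Y[at(n, m)];
    state = 0; score = e0;
    if (e1 > score) { score = e1; state = 1; }
    if (e2 > score) { score = e2; state = 2; }
  }

  std::vector<int> ai, bi;
  while (!(i == 0 && j == 0)) {
    if (state == 0) {
      signed char prev = tbM[at(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      if (local && prev == -1) break;  // fresh start: pair included, stop
      state = prev;
    } else if (state == 1) {
      signed char prev = tbX[at(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      signed char prev = tbY[at(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = score);
}
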