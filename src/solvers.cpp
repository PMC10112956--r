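#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>

using namespace Rcpp;

namespace {

// Block cost oracle over prefix sums of sufficient statistics.
// Columns are 1-based inclusive; prefix arrays have length m+1 with index 0 = 0.
struct CostModel {
  int family;          // 0 = bernoulli, 1 = gaussian
  const double* a;     // bernoulli: ones prefix; gaussian: sum prefix
  const double* b;     // gaussian: sum-of-squares prefix (ignored for bernoulli)
  const double* cnt;   // observed-entry count prefix
  double pw;           // lambda * J(n)
  double vfloor;       // gaussian variance floor
  int regtype;         // 0 = constant-per-block, 1 = physical distance (ROH)
  const double* pos;   // physical positions in bp, length m
  double T;            // minimal admissible block span, megabases
  double beta;         // bp per unit (1e6 -> megabases)

  // negative log-likelihood of block r:s at the block MLE, observed entries only
  double nll(int r, int s) const {
    double N = cnt[s] - cnt[r - 1];
    if (N <= 0.0) return 0.0;  // no observed entries: empty product
    if (family == 0) {
      double S = a[s] - a[r - 1];
      double p = S / N;
      double out = 0.0;
      if (S > 0.0) out -= S * std::log(p);
      if (N - S > 0.0) out -= (N - S) * std::log(1.0 - p);
      return out;
    }
    double sum = a[s] - a[r - 1];
    double ss = b[s] - b[r - 1];
    double mu = sum / N;
    double v = ss / N - mu * mu;
    if (v < vfloor) v = vfloor;
    return 0.5 * N * (std::log(2.0 * M_PI * v) + 1.0);
  }

  double rho(int r, int s) const {
    if (regtype == 0) return 1.0;
    double span = std::fabs(pos[s - 1] - pos[r - 1]) / beta;
    if (span <= T) return R_PosInf;
    return span;
  }

  double q(int r, int s) const {
    double p = rho(r, s);
    if (p == R_PosInf) return R_PosInf;
    return nll(r, s) + pw * p;
  }
};

CostModel make_model(int family, const NumericVector& pa, const NumericVector& pb,
                     const NumericVector& pcnt, double pw, double vfloor,
                     int regtype, const NumericVector& pos, double T, double beta) {
  CostModel cm;
  cm.family = family;
  cm.a = pa.begin();
  cm.b = pb.begin();
  cm.cnt = pcnt.begin();
  cm.pw = pw;
  cm.vfloor = vfloor;
  cm.regtype = regtype;
  cm.pos = pos.begin();
  cm.T = T;
  cm.beta = beta;
  return cm;
}

}  // namespace

// Exact optimal-partitioning recursion F(i) = min_{0<=c<i} F(c) + Q((c+1):i).
// Ties go to the smallest admissible c (leftmost), making the output deterministic.
// [[Rcpp::export]]
IntegerVector dp_solve_cpp(int family, NumericVector pa, NumericVector pb,
                           NumericVector pcnt, double pw, double vfloor,
                           int regtype, NumericVector pos, double T, double beta) {
  const int m = pcnt.size() - 1;
  CostModel cm = make_model(family, pa, pb, pcnt, pw, vfloor, regtype, pos, T, beta);
  std::vector<double> F(m + 1, R_PosInf);
  std::vector<int> back(m + 1, -1);
  F[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    double best = R_PosInf;
    int argc = -1;
    for (int c = 0; c < i; ++c) {
      if (F[c] == R_PosInf) continue;
      double v = F[c] + cm.q(c + 1, i);
      if (v < best) {
        best = v;
        argc = c;
      }
    }
    F[i] = best;
    back[i] = argc;
  }
  if (back[m] < 0 || F[m] == R_PosInf)
    stop("no segmentation with finite penalized cost exists; with physical-distance "
         "regularization the full span must exceed T megabases");
  std::vector<int> pts;
  for (int i = m; i > 0; i = back[i]) pts.push_back(i);
  pts.push_back(0);
  std::reverse(pts.begin(), pts.end());
  return wrap(pts);
}

// Greedy hierarchical (binary) segmentation: split interval I = r:s at the
// leftmost minimizer of h_I(c) = PL(r:c) + PL((c+1):s), only when that strictly
// improves on PL(I); recurse until no interval admits an improving split.
// [[Rcpp::export]]
IntegerVector hs_solve_cpp(int family, NumericVector pa, NumericVector pb,
                           NumericVector pcnt, double pw, double vfloor,
                           int regtype, NumericVector pos, double T, double beta) {
  const int m = pcnt.size() - 1;
  CostModel cm = make_model(family, pa, pb, pcnt, pw, vfloor, regtype, pos, T, beta);
  if (cm.q(1, m) == R_PosInf) {
    // the unsplit interval must be admissible: with one block the PL is q(1, m)
    bool rescued = false;
    for (int c = 1; c < m && !rescued; ++c)
      if (cm.q(1, c) + cm.q(c + 1, m) < R_PosInf) rescued = true;
    if (!rescued)
      stop("no segmentation with finite penalized cost exists; with physical-distance "
           "regularization the full span must exceed T megabases");
  }
  std::vector<int> pts;
  pts.push_back(0);
  pts.push_back(m);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(1, m));
  while (!stack.empty()) {
    int r = stack.back().first;
    int s = stack.back().second;
    stack.pop_back();
    if (s <= r) continue;
    double pli = cm.q(r, s);  // h_I(s) by the PL(empty) = 0 convention
    double best = R_PosInf;
    int argc = -1;
    for (int c = r; c < s; ++c) {
      double v = cm.q(r, c) + cm.q(c + 1, s);
      if (v < best) {
        best = v;
        argc = c;
      }
    }
    if (argc >= 0 && best < pli) {
      pts.push_back(argc);
      stack.push_back(std::make_pair(r, argc));
      stack.push_back(std::make_pair(argc + 1, s));
    }
  }
  std::sort(pts.begin(), pts.end());
  return wrap(pts);
}
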