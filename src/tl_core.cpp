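#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Ties must not adopt (strict inequality); guard against floating noise.
static const double RULE_EPS = 1e-9;

// Binomial pmf row for size a, success prob y, computed outward from the
// mode (one R::dbinom call per row, ratio recurrence for the rest). Stable
// for all y in [0, 1]; entries that underflow are genuinely negligible.
static void binom_row(int a, double y, std::vector<double>& row) {
  row.assign(a + 1, 0.0);
  if (a == 0) { row[0] = 1.0; return; }
  if (y <= 0.0) { row[0] = 1.0; return; }
  if (y >= 1.0) { row[a] = 1.0; return; }
  int m0 = (int)std::floor((a + 1) * y);
  if (m0 > a) m0 = a;
  row[m0] = R::dbinom(m0, a, y, 0);
  const double odds = y / (1.0 - y);
  for (int m = m0; m < a; ++m)
    row[m + 1] = row[m] * ((double)(a - m) / (double)(m + 1)) * odds;
  for (int m = m0; m > 0; --m)
    row[m - 1] = row[m] * ((double)m / (double)(a - m + 1)) / odds;
}

// Tables up to size K: pmf[a][m] and cdf[a][m] = P(Bin(a, y) <= m).
static void binom_tables(int K, double y,
                         std::vector< std::vector<double> >& pmf,
                         std::vector< std::vector<double> >& cdf) {
  pmf.resize(K + 1);
  cdf.resize(K + 1);
  for (int a = 0; a <= K; ++a) {
    binom_row(a, y, pmf[a]);
    cdf[a].assign(a + 1, 0.0);
    double c = 0.0;
    for (int m = 0; m <= a; ++m) { c += pmf[a][m]; cdf[a][m] = c; }
  }
}

// P(w_inter * mB > t) with mB ~ Bin(b, .) given that side's cdf table.
static inline double tail_prob(int b, double t, double w_inter,
                               const std::vector< std::vector<double> >& cdf) {
  if (w_inter > 0.0) {
    double q = t / w_inter;
    int c = (int)std::floor(q + RULE_EPS);
    if (c < 0) return 1.0;
    if (c >= b) return 0.0;
    double v = 1.0 - cdf[b][c];
    return v > 0.0 ? v : 0.0;
  }
  // no inter influence: rule already decided by the intra part
  return (t < -RULE_EPS) ? 1.0 : 0.0;
}

// Cavity update for one community: p1/p2 are the intra/inter degree pmfs
// indexed from degree 0; y_self/y_other are the link-level adoption
// probabilities seen along intra and inter links. The cavity excludes the
// parent link from the adopted-neighbor binomials; `full_threshold` selects
// whether the rule's degree argument is the node's full degree k (the
// degree it actually has in the dynamics, default) or the decremented k-1.
static double comm_update(const NumericVector& p1, const NumericVector& p2,
                          double y_self, double y_other,
                          double w_intra, double w_inter,
                          double theta, bool constant_rule, double C,
                          double rho0, bool full_threshold) {
  const int K1 = p1.size() - 1, K2 = p2.size() - 1;
  double z = 0.0;
  for (int k = 0; k <= K1; ++k) z += k * p1[k];
  for (int k = 0; k <= K2; ++k) z += k * p2[k];
  if (z <= 0.0) return rho0;

  std::vector< std::vector<double> > PA, CA, PB, CB;
  binom_tables(K1, y_self, PA, CA);
  binom_tables(K2, y_other, PB, CB);

  double S = 0.0;
  for (int ki = 0; ki <= K1; ++ki) {
    if (p1[ki] <= 0.0) continue;
    for (int kj = 0; kj <= K2; ++kj) {
      double w = p1[ki] * p2[kj];
      if (w <= 0.0 || ki + kj == 0) continue;
      const int kdeg = full_threshold ? (ki + kj) : (ki + kj - 1);
      const double thr = constant_rule ? C : theta * kdeg;
      double contrib = 0.0;
      if (ki >= 1) { // reached along an intra link: excess intra degree
        const int a = ki - 1, b = kj;
        double s = 0.0;
        for (int mA = 0; mA <= a; ++mA)
          s += PA[a][mA] * tail_prob(b, thr - w_intra * mA, w_inter, CB);
        contrib += ki * s;
      }
      if (kj >= 1) { // reached along an inter link: excess inter degree
        const int a = ki, b = kj - 1;
        double s = 0.0;
        for (int mA = 0; mA <= a; ++mA)
          s += PA[a][mA] * tail_prob(b, thr - w_intra * mA, w_inter, CB);
        contrib += kj * s;
      }
      S += w * contrib;
    }
  }
  S /= z;
  return rho0 + (1.0 - rho0) * S;
}

// Steady-state density for one community (Eq.-10-type sum: full binomials,
// full degree in the threshold, no cavity decrement or degree weighting).
static double comm_rho(const NumericVector& p1, const NumericVector& p2,
                       double y_self, double y_other,
                       double w_intra, double w_inter,
                       double theta, bool constant_rule, double C,
                       double rho0) {
  const int K1 = p1.size() - 1, K2 = p2.size() - 1;
  std::vector< std::vector<double> > PA, CA, PB, CB;
  binom_tables(K1, y_self, PA, CA);
  binom_tables(K2, y_other, PB, CB);

  double S = 0.0;
  for (int ki = 0; ki <= K1; ++ki) {
    if (p1[ki] <= 0.0) continue;
    for (int kj = 0; kj <= K2; ++kj) {
      double w = p1[ki] * p2[kj];
      if (w <= 0.0) continue;
      const double thr = constant_rule ? C : theta * (ki + kj);
      double s = 0.0;
      for (int mA = 0; mA <= ki; ++mA)
        s += PA[ki][mA] * tail_prob(kj, thr - w_intra * mA, w_inter, CB);
      S += w * s;
    }
  }
  return rho0 + (1.0 - rho0) * S;
}

// [[Rcpp::export]]
NumericVector tl_update_two_cpp(List p_intra, List p_inter,
                                NumericVector y, NumericMatrix omega,
                                double theta, bool constant_rule, double C,
                                NumericVector rho0, bool full_threshold) {
  NumericVector p1A = p_intra[0], p1B = p_intra[1];
  NumericVector p2A = p_inter[0], p2B = p_inter[1];
  NumericVector out(2);
  out[0] = comm_update(p1A, p2A, y[0], y[1], omega(0, 0), omega(0, 1),
                       theta, constant_rule, C, rho0[0], full_threshold);
  out[1] = comm_update(p1B, p2B, y[1], y[0], omega(1, 1), omega(1, 0),
                       theta, constant_rule, C, rho0[1], full_threshold);
  return out;
}

// [[Rcpp::export]]
NumericVector tl_rho_two_cpp(List p_intra, List p_inter,
                             NumericVector y, NumericMatrix omega,
                             double theta, bool constant_rule, double C,
                             NumericVector rho0) {
  NumericVector p1A = p_intra[0], p1B = p_intra[1];
  NumericVector p2A = p_inter[0], p2B = p_inter[1];
  NumericVector out(2);
  out[0] = comm_rho(p1A, p2A, y[0], y[1], omega(0, 0), omega(0, 1),
                    theta, constant_rule, C, rho0[0]);
  out[1] = comm_rho(p1B, p2B, y[1], y[0], omega(1, 1), omega(1, 0),
                    theta, constant_rule, C, rho0[1]);
  return out;
}
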