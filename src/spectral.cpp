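#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact per-window spectral-rigidity integrand.
//
// For each window [c, c+L], fits the least-squares line A*lambda + B to the
// level-counting staircase eta(lambda) under the uniform measure on the
// window, and evaluates (1/L) * integral (eta - A*lambda - B)^2 in closed
// form piecewise over the step intervals. The constant offset of eta is
// absorbed by B, so only counts relative to the window start matter.
// Coordinates are shifted by c to avoid cancellation; Var(lambda) = L^2/12
// exactly for the uniform measure.
//
// [[Rcpp::export]]
NumericVector rigidity_windows(NumericVector levels, NumericVector starts, double L) {
  const int nw = starts.size();
  NumericVector out(nw);
  const double *e = levels.begin();
  const double *e_end = levels.end();
  const double var_lam = L * L / 12.0;

  for (int w = 0; w < nw; ++w) {
    const double c = starts[w];
    const double *lo = std::upper_bound(e, e_end, c);        // first level > c
    const double *hi = std::lower_bound(lo, e_end, c + L);   // first level >= c+L
    const int m = hi - lo;                                   // jumps inside window

    // breakpoints (shifted): 0 = x0 < x1 < ... < xm < x_{m+1} = L
    // eta (relative) on [x_j, x_{j+1}) equals j.
    double S1 = 0.0, Slam = 0.0, S2 = 0.0;
    double prev = (m > 0) ? (lo[0] - c) : L;
    for (int j = 1; j <= m; ++j) {
      const double next = (j < m) ? (lo[j] - c) : L;
      const double dj = next - prev;
      S1 += j * dj;
      Slam += j * (next * next - prev * prev) * 0.5;
      S2 += static_cast<double>(j) * j * dj;
      prev = next;
    }
    const double m_eta = S1 / L;
    const double m_lam = L * 0.5;
    const double cov = Slam / L - m_lam * m_eta;
    const double A = cov / var_lam;
    double val = (S2 / L - m_eta * m_eta) - A * A * var_lam;
    out[w] = (val > 0.0) ? val : 0.0;
  }
  return out;
}

// Number of levels in each half-open window [c, c+L).
// [[Rcpp::export]]
IntegerVector window_counts(NumericVector levels, NumericVector starts, double L) {
  const int nw = starts.size();
  IntegerVector out(nw);
  const double *e = levels.begin();
  const double *e_end = levels.end();
  for (int w = 0; w < nw; ++w) {
    const double c = starts[w];
    const double *lo = std::lower_bound(e, e_end, c);
    const double *hi = std::lower_bound(lo, e_end, c + L);
    out[w] = hi - lo;
  }
  return out;
}
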