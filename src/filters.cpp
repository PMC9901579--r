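#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied down the rows of a matrix
// (time along rows, one signal per column). a[0] must be 1. The filter state
// of column p is initialized to zi * x0[p] (steady-state initial conditions
// for a step of height x0[p]); pass a zero-length zi for zero initial state.
// [[Rcpp::export(name = ".df2t_filter_mat")]]
NumericMatrix df2t_filter_mat(NumericVector b, NumericVector a, NumericMatrix x,
                              NumericVector zi, NumericVector x0) {
  const int nb = b.size(), na = a.size();
  const int n = std::max(nb, na);
  const int T = x.nrow(), P = x.ncol();
  NumericMatrix y(T, P);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(n - 1);
  const bool have_zi = zi.size() == n - 1;
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n - 1; ++i) z[i] = have_zi ? zi[i] * x0[p] : 0.0;
    for (int t = 0; t < T; ++t) {
      const double xt = x(t, p);
      const double yt = bb[0] * xt + z[0];
      for (int i = 0; i < n - 2; ++i)
        z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
      z[n - 2] = bb[n - 1] * xt - aa[n - 1] * yt;
      y(t, p) = yt;
    }
  }
  return y;
}

// Uniform running-average temporal filter (odd kernel), shrinking at the
// record boundaries; applied down the rows of a matrix.
// [[Rcpp::export(name = ".running_mean_mat")]]
NumericMatrix running_mean_mat(NumericMatrix x, int k) {
  const int T = x.nrow(), P = x.ncol();
  const int h = k / 2;
  NumericMatrix y(T, P);
  for (int p = 0; p < P; ++p) {
    for (int t = 0; t < T; ++t) {
      const int lo = std::max(0, t - h), hi = std::min(T - 1, t + h);
      double s = 0.0;
      for (int i = lo; i <= hi; ++i) s += x(i, p);
      y(t, p) = s / (hi - lo + 1);
    }
  }
  return y;
}
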