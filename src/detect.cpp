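#include <Rcpp.h>
using namespace Rcpp;

// Batch activation detection over retained windows. Mirrors the reference
// R implementation in detect_upstroke_activations()/filter_windows(): a
// window is kept when its least-squares slope is positive and its maximal
// central-difference derivative reaches theta; the two largest plateau-aware
// derivative peaks split into two events when the relative valley depth
// reaches valley_frac.
//
// m:   T x P signal matrix (time down the rows)
// win: rows of (pixel, start, end), 1-based inclusive
// Returns a matrix with one row per event:
//   (window_row, frame, component (1 primary / 2 secondary), vf_star)
// [[Rcpp::export(name = ".detect_events_batch")]]
NumericMatrix detect_events_batch(NumericMatrix m, IntegerMatrix win,
                                  double theta, double valley_frac,
                                  double dt) {
  const int T = m.nrow();
  std::vector<double> out;
  std::vector<double> d;
  for (int r = 0; r < win.nrow(); ++r) {
    const int px = win(r, 0) - 1, s = win(r, 1) - 1, e = win(r, 2) - 1;
    const int L = e - s + 1;
    if (L < 3) continue;
    // central difference over one frame (one-sided at the record ends)
    d.assign(L, 0.0);
    double amp_lo = m(s, px), amp_hi = m(s, px);
    for (int i = 0; i < L; ++i) {
      const int t = s + i;
      const double lo = (t == 0) ? m(0, px) : m(t - 1, px);
      const double hi = (t == T - 1) ? m(T - 1, px) : m(t + 1, px);
      const double denom = (t == 0 || t == T - 1) ? dt : 2.0 * dt;
      d[i] = (hi - lo) / denom;
      const double v = m(t, px);
      if (v < amp_lo) amp_lo = v;
      if (v > amp_hi) amp_hi = v;
    }
    const double amp = amp_hi - amp_lo;
    if (amp <= 0) continue;
    // least-squares slope of the signal against time
    double sy = 0.0, sty = 0.0;
    const double tbar = (L - 1) / 2.0;
    for (int i = 0; i < L; ++i) sy += m(s + i, px);
    const double ybar = sy / L;
    double stt = 0.0;
    for (int i = 0; i < L; ++i) {
      sty += (i - tbar) * (m(s + i, px) - ybar);
      stt += (i - tbar) * (i - tbar);
    }
    if (!(sty / stt > 0)) continue;            // slope filter
    double dmax = d[0];
    for (int i = 1; i < L; ++i) if (d[i] > dmax) dmax = d[i];
    if (dmax < theta) continue;                // derivative filter
    // plateau-aware local maxima above theta (earliest sample of a run)
    std::vector<int> peaks;
    int i = 0;
    while (i < L) {
      int j = i;
      while (j + 1 < L && d[j + 1] == d[i]) ++j;
      const double vl = (i == 0) ? R_NegInf : d[i - 1];
      const double vr = (j == L - 1) ? R_NegInf : d[j + 1];
      if (d[i] > vl && d[i] > vr && d[i] >= theta) peaks.push_back(i);
      i = j + 1;
    }
    int gm = -1;
    if (peaks.empty()) {
      for (int k = 0; k < L; ++k) if (d[k] == dmax) { gm = k; break; }
      if (d[gm] < theta) continue;
      peaks.push_back(gm);
    }
    bool split = false;
    int p1 = -1, p2 = -1;
    if (peaks.size() >= 2) {
      // two largest peaks, earliest first on ties
      int a = peaks[0];
      for (size_t k = 1; k < peaks.size(); ++k)
        if (d[peaks[k]] > d[a]) a = peaks[k];
      int b = -1;
      for (size_t k = 0; k < peaks.size(); ++k) {
        const int c = peaks[k];
        if (c == a) continue;
        if (b < 0 || d[c] > d[b]) b = c;
      }
      p1 = std::min(a, b); p2 = std::max(a, b);
      const double smaller = std::min(d[p1], d[p2]);
      double valley = d[p1];
      for (int k = p1; k <= p2; ++k) if (d[k] < valley) valley = d[k];
      if (smaller > 0 && (smaller - valley) / smaller >= valley_frac)
        split = true;
    }
    if (split) {
      out.push_back(r + 1); out.push_back(s + p1 + 1);
      out.push_back(1); out.push_back(d[p1] * dt / amp);
      out.push_back(r + 1); out.push_back(s + p2 + 1);
      out.push_back(2); out.push_back(d[p2] * dt / amp);
    } else {
      int best = peaks[0];
      for (size_t k = 1; k < peaks.size(); ++k)
        if (d[peaks[k]] > d[best]) best = peaks[k];
      out.push_back(r + 1); out.push_back(s + best + 1);
      out.push_back(1); out.push_back(d[best] * dt / amp);
    }
  }
  const int n = out.size() / 4;
  NumericMatrix res(n, 4);
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < 4; ++c) res(k, c) = out[4 * k + c];
  colnames(res) = CharacterVector::create("window_row", "frame",
                                          "component", "vf_star");
  return res;
}

// Per-window maximal derivative and length plus the per-pixel robust noise
// scale, for the automated threshold (same derivative estimator).
// [[Rcpp::export(name = ".window_max_deriv")]]
NumericMatrix window_max_deriv(NumericMatrix m, IntegerMatrix win, double dt) {
  const int T = m.nrow();
  NumericMatrix res(win.nrow(), 2);
  for (int r = 0; r < win.nrow(); ++r) {
    const int px = win(r, 0) - 1, s = win(r, 1) - 1, e = win(r, 2) - 1;
    double vmax = R_NegInf;
    for (int t = s; t <= e; ++t) {
      const double lo = (t == 0) ? m(0, px) : m(t - 1, px);
      const double hi = (t == T - 1) ? m(T - 1, px) : m(t + 1, px);
      const double denom = (t == 0 || t == T - 1) ? dt : 2.0 * dt;
      const double d = (hi - lo) / denom;
      if (d > vmax) vmax = d;
    }
    res(r, 0) = vmax;
    res(r, 1) = e - s + 1;
  }
  return res;
}
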