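#include <Rcpp.h>
using namespace Rcpp;

// Two-variable excitable-medium (Aliev-Panfilov-type) explicit Euler stepper.
//   du/dt = -k u (u - a)(u - 1) - u v + D lap(u)
//   dv/dt = (eps0 + mu1 v / (u + mu2)) * (-v - k u (u - a - 1))
// Dimensionless model time; the R wrapper owns the ms scaling, stimulus
// injection and frame recording. No-flux (mirror) boundaries. u and v are
// modified in place.
// [[Rcpp::export(name = ".ap_advance")]]
void ap_advance(NumericMatrix u, NumericMatrix v, int nsteps, double dt,
                double k, double a, double eps0, double mu1, double mu2,
                double D) {
  const int nx = u.nrow(), ny = u.ncol();
  NumericMatrix un(nx, ny);
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 1 : j - 1;
      const int jp = (j == ny - 1) ? ny - 2 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i == 0) ? 1 : i - 1;
        const int ip = (i == nx - 1) ? nx - 2 : i + 1;
        const double uc = u(i, j), vc = v(i, j);
        const double lap = u(im, j) + u(ip, j) + u(i, jm) + u(i, jp) - 4.0 * uc;
        const double du = -k * uc * (uc - a) * (uc - 1.0) - uc * vc + D * lap;
        const double eps = eps0 + mu1 * vc / (uc + mu2);
        const double dv = eps * (-vc - k * uc * (uc - a - 1.0));
        un(i, j) = uc + dt * du;
        v(i, j) = vc + dt * dv;
      }
    }
    std::copy(un.begin(), un.end(), u.begin());
  }
}
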