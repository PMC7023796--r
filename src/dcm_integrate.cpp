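#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear neural + balloon-Windkessel hemodynamic forward model.
//
// Per-region state: (z, s, f, lv, lq) with lv = log v, lq = log q so that
// blood volume and deoxyhemoglobin content stay positive for any step size.
//
// dz  = A z + u * (B z) + C u           (single driving input)
// ds  = z - kappa*s - gamma*(f - 1)
// df  = s
// dlv = (f - v^(1/alpha)) / (tau * v)
// dlq = (f*(1-(1-E0)^(1/f))/E0 - v^(1/alpha) * q / v) / (tau * q)
//
// BOLD (fractional): y = V0 * (k1*(1-q) + k2*(1-q/v) + k3*(1-v)),
// k1 = 7*E0, k2 = 2, k3 = 2*E0 - 0.2.  Output is scaled to percent.

namespace {

struct HemoConst {
  double kappa, gamma, tau, alpha, E0, V0;
};

// boxcar stimulus: 1 on [onset, onset+duration), else 0
inline double boxcar(double t, const std::vector<double>& on,
                     const std::vector<double>& off) {
  for (size_t i = 0; i < on.size(); ++i) {
    if (t >= on[i] && t < off[i]) return 1.0;
    if (t < on[i]) break;  // onsets strictly increasing, non-overlapping
  }
  return 0.0;
}

inline void deriv(const std::vector<double>& x, double u, int n,
                  const std::vector<double>& A, const std::vector<double>& B,
                  bool hasB, const std::vector<double>& Cvec,
                  const HemoConst& h, std::vector<double>& dx) {
  // x layout: [z_1..z_n, s_1..s_n, f_1..f_n, lv_1..lv_n, lq_1..lq_n]
  const double* z = x.data();
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = A[i + n * j];
      if (hasB) a += u * B[i + n * j];
      acc += a * z[j];
    }
    dx[i] = acc + Cvec[i] * u;
  }
  const double ooalpha = 1.0 / h.alpha;
  for (int i = 0; i < n; ++i) {
    double zi = z[i];
    double s = x[n + i];
    double f = x[2 * n + i];
    double v = std::exp(x[3 * n + i]);
    double q = std::exp(x[4 * n + i]);
    double fv = std::pow(v, ooalpha);  // outflow
    dx[n + i] = zi - h.kappa * s - h.gamma * (f - 1.0);
    dx[2 * n + i] = s;
    dx[3 * n + i] = (f - fv) / (h.tau * v);
    double E = 1.0 - std::pow(1.0 - h.E0, 1.0 / f);  // extraction at flow f
    dx[4 * n + i] = (f * E / h.E0 - fv * q / v) / (h.tau * q);
  }
}

}  // namespace

// [[Rcpp::export(name = ".dcm_integrate_cpp")]]
NumericMatrix dcm_integrate_cpp(NumericMatrix A, NumericVector Cvec,
                                Nullable<NumericMatrix> Bmat,
                                NumericVector onsets, NumericVector durations,
                                double TR, int nScans, double dt,
                                NumericVector hemo) {
  const int n = A.nrow();
  if (A.ncol() != n || Cvec.size() != n)
    stop("dimension mismatch between A and C");
  if (hemo.size() != 6) stop("hemo must have 6 entries");
  HemoConst h{hemo[0], hemo[1], hemo[2], hemo[3], hemo[4], hemo[5]};

  std::vector<double> Av(A.begin(), A.end());
  std::vector<double> Bv;
  bool hasB = false;
  if (Bmat.isNotNull()) {
    NumericMatrix Bm(Bmat);
    if (Bm.nrow() != n || Bm.ncol() != n) stop("B dimension mismatch");
    Bv.assign(Bm.begin(), Bm.end());
    for (double b : Bv)
      if (b != 0.0) { hasB = true; break; }
  }
  std::vector<double> Cv(Cvec.begin(), Cvec.end());
  std::vector<double> on(onsets.begin(), onsets.end());
  std::vector<double> off(on.size());
  for (size_t i = 0; i < on.size(); ++i) off[i] = on[i] + durations[i];

  const int stepsPerScan = (int)std::lround(TR / dt);
  if (stepsPerScan < 1 || std::fabs(stepsPerScan * dt - TR) > 1e-9 * TR)
    stop("dt must divide TR");

  const int dim = 5 * n;
  std::vector<double> x(dim, 0.0);
  for (int i = 0; i < n; ++i) {  // rest: z=0, s=0, f=1, v=1, q=1
    x[2 * n + i] = 1.0;
    x[3 * n + i] = 0.0;
    x[4 * n + i] = 0.0;
  }
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), xt(dim);

  NumericMatrix out(nScans, n);
  const double k1c = 7.0 * h.E0, k2c = 2.0, k3c = 2.0 * h.E0 - 0.2;

  double t = 0.0;
  for (int scan = 0; scan < nScans; ++scan) {
    for (int step = 0; step < stepsPerScan; ++step) {
      // the boxcar is piecewise constant: use its mid-step value for all
      // four stages, so steps aligned with on/off switches keep full order
      double u = boxcar(t + 0.5 * dt, on, off);
      deriv(x, u, n, Av, Bv, hasB, Cv, h, k1);
      for (int i = 0; i < dim; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
      deriv(xt, u, n, Av, Bv, hasB, Cv, h, k2);
      for (int i = 0; i < dim; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
      deriv(xt, u, n, Av, Bv, hasB, Cv, h, k3);
      for (int i = 0; i < dim; ++i) xt[i] = x[i] + dt * k3[i];
      deriv(xt, u, n, Av, Bv, hasB, Cv, h, k4);
      for (int i = 0; i < dim; ++i)
        x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      t += dt;
      for (int i = 0; i < dim; ++i) {
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6)
          stop("dcm_integrate: state diverged (|state| > 1e6)");
      }
    }
    // sample BOLD at t = (scan+1)*TR
    for (int i = 0; i < n; ++i) {
      double v = std::exp(x[3 * n + i]);
      double q = std::exp(x[4 * n + i]);
      out(scan, i) =
          100.0 * h.V0 * (k1c * (1.0 - q) + k2c * (1.0 - q / v) + k3c * (1.0 - v));
    }
  }
  return out;
}
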