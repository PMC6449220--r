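#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener process with drift at the LOWER of two
// absorbing boundaries (0 and a), start z = w*a, drift v, diffusion coefficient s.
// Series representation with small-time / large-time switching; truncation chosen
// so the absolute error of the standardized density is below eps.

static double fpt_lower_std(double tau, double w, double eps) {
  // density for unit boundary separation, zero drift, scaled time tau
  if (tau <= 0.0) return 0.0;
  double ks = 2.0 + std::sqrt(std::max(0.0, -2.0 * tau *
                    std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau))));
  ks = std::max(ks, std::sqrt(tau) + 1.0);
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps >= 1.0) ks = 2.0;
  double kl = std::sqrt(std::max(0.0, -2.0 * std::log(M_PI * tau * eps) /
                    (M_PI * M_PI * tau)));
  kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  if (M_PI * tau * eps >= 1.0) kl = 1.0 / (M_PI * std::sqrt(tau));

  double f0 = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(K - 1) / 2, hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      f0 += u * std::exp(-u * u / (2.0 * tau));
    }
    f0 /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f0 += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
            std::sin(k * M_PI * w);
    }
    f0 *= M_PI;
  }
  return f0;
}

// [[Rcpp::export]]
NumericVector wiener_fpt_lower_cpp(NumericVector t, double v, double a,
                                   double w, double s, double eps) {
  double vv = v / s, aa = a / s;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ti = t[i];
    if (!(ti > 0.0)) { out[i] = 0.0; continue; }
    double tau = ti / (aa * aa);
    double f0 = fpt_lower_std(tau, w, eps);
    double lg = -vv * aa * w - vv * vv * ti / 2.0;
    out[i] = f0 * std::exp(lg) / (aa * aa);
    if (out[i] < 0.0) out[i] = 0.0; // guard truncation noise near 0
  }
  return out;
}

// Euler-Maruyama simulation of the (full) diffusion with Brownian-bridge
// boundary-crossing correction inside each step. Uses R's RNG so set.seed()
// governs reproducibility. Returns decision time, boundary and the trial-level
// parameter draws actually used.
// [[Rcpp::export]]
List sim_diffusion_cpp(int n, double v, double a, double zr, double ter,
                       double s, double sv, double szr, double st,
                       double dt, double deadline) {
  NumericVector rt(n);
  IntegerVector upper(n);   // 1 = upper boundary, 0 = lower, NA = timed out
  LogicalVector timed_out(n);
  double s2dt = s * s * dt;
  double sqdt = s * std::sqrt(dt);
  // crossing probability below exp(-27) ~ 2e-12 is ignored
  double skip = 27.0 * s2dt / 2.0;

  for (int i = 0; i < n; ++i) {
    double vi = sv > 0.0 ? R::rnorm(v, sv) : v;
    double zi = szr > 0.0 ? a * R::runif(zr - szr / 2.0, zr + szr / 2.0) : a * zr;
    double ti = st > 0.0 ? R::runif(ter - st / 2.0, ter + st / 2.0) : ter;
    double tmax = deadline - ti;  // decision-time budget
    double x = zi, tdec = 0.0;
    int hit = NA_INTEGER;
    while (tdec < tmax) {
      double xn = x + vi * dt + sqdt * norm_rand();
      tdec += dt;
      if (xn >= a) { hit = 1; break; }
      if (xn <= 0.0) { hit = 0; break; }
      // bridge correction for an excursion within the step
      double du = (a - x) * (a - xn);
      if (du < skip) {
        if (unif_rand() < std::exp(-2.0 * du / s2dt)) { hit = 1; break; }
      }
      double dl = x * xn;
      if (dl < skip) {
        if (unif_rand() < std::exp(-2.0 * dl / s2dt)) { hit = 0; break; }
      }
      x = xn;
    }
    if (hit == NA_INTEGER || tdec + ti > deadline) {
      rt[i] = deadline;
      timed_out[i] = true;
      upper[i] = NA_INTEGER;
    } else {
      rt[i] = tdec + ti;
      timed_out[i] = false;
      upper[i] = hit;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper,
                      _["timed_out"] = timed_out);
}
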