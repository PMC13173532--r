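#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// U(x) = dU * ((x/a)^2 - 1)^2  =>  U'(x) = 4 dU x / a^2 * ((x/a)^2 - 1)
static inline double dUdx(double x, double dU, double a) {
  double r = x / a;
  return 4.0 * dU * x / (a * a) * (r * r - 1.0);
}

// Overdamped Euler-Maruyama on the double well, recording every `stride`
// steps (frame 0 = x0). Uses R's RNG: seeding happens on the R side.
// [[Rcpp::export]]
List sim_double_well_cpp(double dU, double a, double gam, double kT,
                         double n_steps_d, double dt, double x0, int stride) {
  long long n_steps = (long long)n_steps_d;
  std::vector<double> xs;
  xs.reserve((size_t)(n_steps / stride) + 2);
  double x = x0;
  const double noise = std::sqrt(2.0 * kT * dt / gam);
  xs.push_back(x);
  for (long long i = 1; i <= n_steps; ++i) {
    x += -dUdx(x, dU, a) / gam * dt + noise * R::norm_rand();
    if (std::fabs(x) > 10.0 * a)
      return List::create(_["unstable"] = true, _["x"] = NumericVector(0));
    if (i % stride == 0) xs.push_back(x);
  }
  return List::create(_["unstable"] = false, _["x"] = wrap(xs));
}

// First-passage time of the unbiased dynamics to x >= threshold.
// [[Rcpp::export]]
List unbiased_fpt_cpp(double dU, double a, double gam, double kT, double dt,
                      double x0, double threshold, double max_steps_d) {
  long long max_steps = (long long)max_steps_d;
  double x = x0;
  const double noise = std::sqrt(2.0 * kT * dt / gam);
  for (long long i = 0; i <= max_steps; ++i) {
    if (x >= threshold)
      return List::create(_["crossed"] = true, _["fpt"] = (double)i * dt,
                          _["unstable"] = false);
    x += -dUdx(x, dU, a) / gam * dt + noise * R::norm_rand();
    if (std::fabs(x) > 10.0 * a)
      return List::create(_["crossed"] = false, _["fpt"] = NA_REAL,
                          _["unstable"] = true);
  }
  return List::create(_["crossed"] = false, _["fpt"] = NA_REAL,
                      _["unstable"] = false);
}

// Gaussian-hill biased escape on the double well. The CV is the affine
// image of the latent coordinate, s = c0 + c1 * x; hills of height hill_h
// (energy units) and width hill_w (CV units) are deposited at the current s
// every 1/pace time units (never at t = 0). Bias energy is evaluated by
// direct summation over deposited hills. A deposited hill acts from the
// next force evaluation onward. Well-tempered scaling applies when
// biasfactor > 1. The rescaled clock t* accumulates dt * exp(V/kT) as a
// left Riemann sum, so t* over [0, tau] uses the bias seen before each step.
// [[Rcpp::export]]
List biased_escape_cpp(double dU, double a, double gam, double kT, double dt,
                       double x0, double c0, double c1, double hill_h,
                       double hill_w, double pace, double biasfactor,
                       bool stop_on_cv, double threshold, double max_steps_d,
                       int stride) {
  long long max_steps = (long long)max_steps_d;
  std::vector<double> xs, Vs, hc, hh, ht;
  xs.reserve((size_t)(max_steps / stride) + 2);
  Vs.reserve((size_t)(max_steps / stride) + 2);
  double x = x0, tstar = 0.0, fpt = NA_REAL;
  bool crossed = false, unstable = false;
  const double noise = std::sqrt(2.0 * kT * dt / gam);
  const double w2 = hill_w * hill_w;
  long long dep_every = 0;
  if (pace > 0.0 && hill_h > 0.0)
    dep_every = std::max((long long)1, (long long)std::llround(1.0 / (pace * dt)));
  for (long long i = 0; i <= max_steps; ++i) {
    double s = c0 + c1 * x;
    double V = 0.0, dVds = 0.0;
    for (size_t k = 0; k < hc.size(); ++k) {
      double d = s - hc[k];
      double e = hh[k] * std::exp(-0.5 * d * d / w2);
      V += e;
      dVds += -d / w2 * e;
    }
    if (i % stride == 0) {
      xs.push_back(x);
      Vs.push_back(V / kT);
    }
    double coord = stop_on_cv ? s : x;
    if (coord >= threshold) {
      crossed = true;
      fpt = (double)i * dt;
      break;
    }
    if (i == max_steps) break;
    if (dep_every > 0 && i > 0 && (i % dep_every == 0)) {
      double h = hill_h;
      if (biasfactor > 1.0) h *= std::exp(-V / ((biasfactor - 1.0) * kT));
      hc.push_back(s);
      hh.push_back(h);
      ht.push_back((double)i * dt);
    }
    tstar += dt * std::exp(V / kT);
    double F = -dUdx(x, dU, a) - c1 * dVds;
    x += F / gam * dt + noise * R::norm_rand();
    if (std::fabs(x) > 10.0 * a) {
      unstable = true;
      break;
    }
  }
  return List::create(
      _["unstable"] = unstable, _["crossed"] = crossed, _["fpt"] = fpt,
      _["tstar"] = tstar, _["x"] = wrap(xs), _["V"] = wrap(Vs),
      _["hill_time"] = wrap(ht), _["hill_center"] = wrap(hc),
      _["hill_height"] = wrap(hh));
}
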