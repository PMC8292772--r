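// Bootstrap particle filter for the stochastic gLV state-space model:
// Euler-Maruyama propagation of absolute abundances with multiplicative
// Wiener noise between observation times, multinomial read-count
// weighting, systematic resampling at every observation.
//
// Uses R's RNG throughout so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".pfLogLikCpp")]]
List pfLogLikCpp(NumericMatrix counts, NumericVector obsTimes,
                 NumericVector r, NumericMatrix B, NumericVector sigma,
                 NumericVector init, double dt, int nParticles) {
  const int T = counts.nrow();
  const int n = counts.ncol();
  const double sqdt = std::sqrt(dt);

  std::vector<double> part(nParticles * n), tmp(nParticles * n);
  for (int j = 0; j < nParticles; ++j)
    for (int i = 0; i < n; ++i) part[j * n + i] = init[i];

  std::vector<double> logw(nParticles), w(nParticles), drift(n);
  std::vector<int> floorRun(nParticles * n, 0);
  double ll = 0.0;
  bool collapsed = false;
  bool stochastic = false;
  for (int i = 0; i < n; ++i) if (sigma[i] > 0.0) stochastic = true;

  // per-sample multinomial normalizing constants (theta-independent but
  // included so the value is an honest log pmf)
  std::vector<double> logConst(T);
  for (int t = 0; t < T; ++t) {
    double V = 0.0, s = 0.0;
    for (int i = 0; i < n; ++i) {
      V += counts(t, i);
      s += R::lgammafn(counts(t, i) + 1.0);
    }
    logConst[t] = R::lgammafn(V + 1.0) - s;
  }

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      const int nsteps = (int)std::lround((obsTimes[t] - obsTimes[t - 1]) / dt);
      for (int s = 0; s < nsteps; ++s) {
        for (int j = 0; j < nParticles; ++j) {
          double *N = &part[j * n];
          double tot = 0.0;
          for (int i = 0; i < n; ++i) {
            double g = r[i];
            for (int k = 0; k < n; ++k) g += B(i, k) * N[k];
            drift[i] = N[i] * g;
          }
          for (int i = 0; i < n; ++i) {
            N[i] += drift[i] * dt;
            if (stochastic && sigma[i] > 0.0)
              N[i] += sigma[i] * N[i] * sqdt * norm_rand();
            tot += N[i];
          }
          // positivity floor: clamp at 1e-10 of the current total,
          // absorb at 0 after 5 consecutive clamped steps
          double floorv = 1e-10 * std::fabs(tot);
          if (floorv <= 0.0) floorv = 1e-300;
          int *run = &floorRun[j * n];
          for (int i = 0; i < n; ++i) {
            if (N[i] < floorv) {
              run[i] += 1;
              N[i] = (run[i] >= 5) ? 0.0 : floorv;
            } else run[i] = 0;
          }
        }
      }
    }

    // multinomial log-weights
    double maxw = R_NegInf;
    for (int j = 0; j < nParticles; ++j) {
      const double *N = &part[j * n];
      double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += N[i];
      double lw;
      if (!(tot > 0.0)) {
        lw = R_NegInf;
      } else {
        lw = logConst[t];
        for (int i = 0; i < n; ++i) {
          double c = counts(t, i);
          if (c > 0.0) {
            double p = N[i] / tot;
            if (p <= 0.0) { lw = R_NegInf; break; }
            lw += c * std::log(p);
          }
        }
      }
      logw[j] = lw;
      if (lw > maxw) maxw = lw;
    }

    if (!R_FINITE(maxw)) { collapsed = true; ll = R_NegInf; break; }

    double sumw = 0.0;
    for (int j = 0; j < nParticles; ++j) {
      w[j] = std::exp(logw[j] - maxw);
      sumw += w[j];
    }
    ll += maxw + std::log(sumw / nParticles);

    // systematic resampling
    double u = unif_rand() / nParticles;
    double cum = w[0] / sumw;
    int j = 0;
    for (int m = 0; m < nParticles; ++m) {
      double target = u + (double)m / nParticles;
      while (cum < target && j < nParticles - 1) {
        ++j;
        cum += w[j] / sumw;
      }
      for (int i = 0; i < n; ++i) tmp[m * n + i] = part[j * n + i];
    }
    std::swap(part, tmp);
    std::fill(floorRun.begin(), floorRun.end(), 0);
  }

  return List::create(Named("logLik") = ll,
                      Named("collapsed") = collapsed);
}
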