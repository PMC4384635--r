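#include <Rcpp.h>
using namespace Rcpp;

// Species order: M, P, MM, PM (concentrations in uM; rates k1, k3 in uM^-1 s^-1).
static inline void rhs(const double *y, double *dy,
                       double k1, double km1, double k2,
                       double k3, double km3, double k4) {
  const double f1 = k1 * y[0] * y[0] - km1 * y[2];
  const double f3 = k3 * y[1] * y[0] - km3 * y[3];
  dy[0] = -2.0 * f1 + k2 * y[2] - f3;
  dy[1] = k2 * y[2] - f3 + 2.0 * k4 * y[3];
  dy[2] = f1 - k2 * y[2];
  dy[3] = f3 - k4 * y[3];
}

// Fixed-step explicit Euler integration of the trans-autophosphorylation
// scheme, recording the state at each requested output time. Serves as a
// brute-force reference for the adaptive solver; step sizes around 1e-3 s
// keep the fastest process (complex dissociation, ~20 s^-1) well resolved.
// [[Rcpp::export(name = ".euler_progress")]]
NumericMatrix euler_progress(NumericVector t_out, double total0_uM,
                             double k1, double km1, double k2,
                             double k3, double km3, double k4,
                             double h) {
  const int nt = t_out.size();
  NumericMatrix out(nt, 4);
  double y[4] = {total0_uM, 0.0, 0.0, 0.0};
  double dy[4];
  double t = 0.0;
  for (int i = 0; i < nt; ++i) {
    const double target = t_out[i];
    while (t < target) {
      double step = h;
      if (t + step > target) step = target - t;
      rhs(y, dy, k1, km1, k2, k3, km3, k4);
      for (int j = 0; j < 4; ++j) y[j] += step * dy[j];
      t += step;
    }
    for (int j = 0; j < 4; ++j) out(i, j) = y[j];
  }
  return out;
}

// Exact stochastic simulation (Gillespie direct method) of the same scheme
// in a small virtual volume. Returns per-time-point ensemble mean and sd of
// each species (in uM) over nrep independent runs. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".ssa_progress")]]
List ssa_progress(NumericVector t_out, double total0_uM, double volume_L,
                  double k1, double km1, double k2,
                  double k3, double km3, double k4,
                  int nrep) {
  const double NA_CONST = 6.02214e23;
  // uM represented by one molecule in this volume
  const double u = 1.0 / (NA_CONST * volume_L * 1e-6);
  const int n0 = (int)std::lround(total0_uM / u);
  const int nt = t_out.size();

  NumericMatrix sum(nt, 4), sumsq(nt, 4);
  NumericVector fsum(nt), fsumsq(nt);

  for (int r = 0; r < nrep; ++r) {
    long nM = n0, nP = 0, nMM = 0, nPM = 0;
    double t = 0.0;
    for (int i = 0; i < nt; ++i) {
      const double target = t_out[i];
      while (t < target) {
        const double a1 = k1 * u * (double)nM * (double)(nM - 1); // M+M -> MM
        const double a2 = km1 * (double)nMM;                      // MM -> M+M
        const double a3 = k2 * (double)nMM;                       // MM -> P+M
        const double a4 = k3 * u * (double)nP * (double)nM;       // P+M -> PM
        const double a5 = km3 * (double)nPM;                      // PM -> P+M
        const double a6 = k4 * (double)nPM;                       // PM -> P+P
        const double a0 = a1 + a2 + a3 + a4 + a5 + a6;
        if (a0 <= 0.0) { t = target; break; }
        t += R::exp_rand() / a0;
        if (t > target) break;
        const double pick = R::unif_rand() * a0;
        if (pick < a1)                          { nM -= 2; nMM += 1; }
        else if (pick < a1 + a2)                { nM += 2; nMM -= 1; }
        else if (pick < a1 + a2 + a3)           { nMM -= 1; nP += 1; nM += 1; }
        else if (pick < a1 + a2 + a3 + a4)      { nP -= 1; nM -= 1; nPM += 1; }
        else if (pick < a1 + a2 + a3 + a4 + a5) { nPM -= 1; nP += 1; nM += 1; }
        else                                    { nPM -= 1; nP += 2; }
      }
      const double vals[4] = {nM * u, nP * u, nMM * u, nPM * u};
      for (int j = 0; j < 4; ++j) {
        sum(i, j) += vals[j];
        sumsq(i, j) += vals[j] * vals[j];
      }
      const double frac = (double)(nP + nPM) / (double)n0;
      fsum[i] += frac;
      fsumsq[i] += frac * frac;
    }
  }

  NumericMatrix mean(nt, 4), sd(nt, 4);
  NumericVector fmean(nt), fsd(nt);
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < 4; ++j) {
      const double m = sum(i, j) / nrep;
      mean(i, j) = m;
      const double var = (sumsq(i, j) - nrep * m * m) / (nrep - 1);
      sd(i, j) = var > 0.0 ? std::sqrt(var) : 0.0;
    }
    const double fm = fsum[i] / nrep;
    fmean[i] = fm;
    const double fvar = (fsumsq[i] - nrep * fm * fm) / (nrep - 1);
    fsd[i] = fvar > 0.0 ? std::sqrt(fvar) : 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = sd,
                      _["frac_mean"] = fmean, _["frac_sd"] = fsd,
                      _["nrep"] = nrep, _["molecules0"] = n0);
}
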