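// 1D reaction-diffusion FRAP stepper.
//
// Species per grid cell: a (free fluorescent), c (bound fluorescent),
// ab (free bleached), cb (bound bleached). Bound species are immobile.
// Diffusion: conservative flux-form explicit update (reflecting or
// periodic). Reaction: reversible binding to immobile centres; in the
// linearised regime (sigmaFree constant) the per-cell 2-species linear
// ODE is advanced by its closed-form exponential, so the only stability
// bound is the diffusive CFL condition enforced by the caller. In
// saturating mode (sites depleted by occupancy) the reaction is advanced
// explicitly and the caller must also bound dt by the reaction rate.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List frapSimC(NumericVector a0, NumericVector c0,
              NumericVector ab0, NumericVector cb0,
              double D, double konSigma, double koff,
              double kon, double sigmaTot, bool saturating,
              double dx, double dt, int nSteps,
              IntegerVector recordAt, IntegerVector winIdx,
              NumericVector winWgt, bool periodic) {
  const int n = a0.size();
  const int nr = recordAt.size();
  const int nw = winIdx.size();
  double wgtSum = 0.0;
  for (int k = 0; k < nw; ++k) wgtSum += winWgt[k];
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> ab(ab0.begin(), ab0.end());
  std::vector<double> cb(cb0.begin(), cb0.end());
  std::vector<double> tmp(n);

  const double r = D * dt / (dx * dx);
  const double pq = konSigma + koff;
  const double edec = (pq > 0.0) ? std::exp(-pq * dt) : 1.0;
  const double feq = (pq > 0.0) ? koff / pq : 1.0;  // equilibrium free frac

  NumericVector sig(nr), mass(nr);
  int ri = 0;
  bool negative = false;

  for (int s = 0; s <= nSteps; ++s) {
    if (ri < nr && recordAt[ri] == s) {
      double wsum = 0.0, msum = 0.0;
      for (int k = 0; k < nw; ++k) {
        int i = winIdx[k];
        wsum += winWgt[k] * (a[i] + c[i]);
      }
      for (int i = 0; i < n; ++i) msum += a[i] + c[i] + ab[i] + cb[i];
      sig[ri] = wsum / wgtSum;
      mass[ri] = msum * dx;
      ++ri;
    }
    if (s == nSteps) break;

    // diffusion of the mobile species (flux form, exactly conservative)
    if (D > 0.0) {
      for (int sp = 0; sp < 2; ++sp) {
        std::vector<double>& u = (sp == 0) ? a : ab;
        if (periodic) {
          for (int i = 0; i < n; ++i) {
            int im = (i == 0) ? n - 1 : i - 1;
            int ip = (i == n - 1) ? 0 : i + 1;
            tmp[i] = u[i] + r * (u[ip] - 2.0 * u[i] + u[im]);
          }
        } else {
          tmp[0] = u[0] + r * (u[1] - u[0]);
          for (int i = 1; i < n - 1; ++i)
            tmp[i] = u[i] + r * (u[i + 1] - 2.0 * u[i] + u[i - 1]);
          tmp[n - 1] = u[n - 1] + r * (u[n - 2] - u[n - 1]);
        }
        u.swap(tmp);
      }
    }

    // reaction
    if (konSigma > 0.0 || (saturating && kon > 0.0)) {
      if (!saturating) {
        // exact update of the linear pair (a, c): a+c conserved per cell
        for (int i = 0; i < n; ++i) {
          double s1 = a[i] + c[i];
          a[i] = feq * s1 + (a[i] - feq * s1) * edec;
          c[i] = s1 - a[i];
          double s2 = ab[i] + cb[i];
          ab[i] = feq * s2 + (ab[i] - feq * s2) * edec;
          cb[i] = s2 - ab[i];
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double sf = sigmaTot - c[i] - cb[i];
          if (sf < 0.0) sf = 0.0;
          double f1 = (kon * a[i] * sf - koff * c[i]) * dt;
          double f2 = (kon * ab[i] * sf - koff * cb[i]) * dt;
          a[i] -= f1; c[i] += f1;
          ab[i] -= f2; cb[i] += f2;
        }
      }
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i)
        if (a[i] < -1e-9 || c[i] < -1e-9 || ab[i] < -1e-9 || cb[i] < -1e-9)
          negative = true;
      if (negative) break;
    }
  }

  return List::create(_["signal"] = sig, _["mass"] = mass,
                      _["negative"] = negative);
}
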