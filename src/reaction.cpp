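// Reaction sub-step of the operator-split reaction-diffusion solver.
//
// Each interior pixel carries seven species (rho, rhod, dia, rock, rac,
// racd, pak).  Within a reaction sub-step the per-pixel GTPase totals
// rho+rhod and rac+racd are invariant, so the kinetics reduce to five
// ODEs per pixel, integrated independently with an adaptive embedded
// Cash-Karp Runge-Kutta 5(4) scheme.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// parameter order expected from R (see .cppParamVector)
enum ParIdx {
  iVGEFRho, iKGEFRho, iVGAPRho, iKGAPRho,
  iVaDIA, iKaDIA, iViDIA, iKiDIA,
  iVaROCK, iKaROCK, iViROCK, iKiROCK,
  iVGEFRac, iKGEFRac, iVGAPRac, iKGAPRac,
  iVaPAK, iKaPAK, iViPAK, iKiPAK,
  iGDIARho, iKDIARho, iGPAKRho, iKPAKRho,
  iGRhoDIA, iKRhoDIA, iGRhoROCK, iKRhoROCK,
  iGDIARac, iKDIARac, iGPAKRac, iKPAKRac,
  iGROCKRac, iKROCKRac, iGRacPAK, iKRacPAK,
  iP, iBeta, iKaScale, NPAR
};

static inline double phi(double u) { return u / (1.0 + u); }

static inline double alpha(double a, double g, double k) {
  double u = a / k;
  return (1.0 + g * u) / (1.0 + u);
}

// five-variable reaction rates at one pixel; x = {rho, dia, rock, rac, pak}
static inline void rhs5(const double* x, const double* v,
                        double rhoT, double racT, double d, double r,
                        double* f) {
  const double rho = x[0], dia = x[1], rock = x[2], rac = x[3], pak = x[4];
  const double aDIARho  = alpha(dia,  v[iGDIARho],  v[iKDIARho]);
  const double aPAKRho  = alpha(pak,  v[iGPAKRho],  v[iKPAKRho]);
  const double aRhoDIA  = alpha(rho,  v[iGRhoDIA],  v[iKRhoDIA]);
  const double aRhoROCK = alpha(rho,  v[iGRhoROCK], v[iKRhoROCK]);
  const double aDIARac  = alpha(dia,  v[iGDIARac],  v[iKDIARac]);
  const double aPAKRac  = alpha(pak,  v[iGPAKRac],  v[iKPAKRac]);
  const double aROCKRac = alpha(v[iBeta] * rock, v[iGROCKRac], v[iKROCKRac]);
  const double aRacPAK  = alpha(rac,  v[iGRacPAK], v[iKRacPAK]);
  const double kaPAK = v[iKaPAK] * v[iKaScale];
  f[0] = v[iVGEFRho] * aDIARho * aPAKRho * phi((rhoT - rho) / v[iKGEFRho]) -
         v[iVGAPRho] * phi(rho / v[iKGAPRho]);
  f[1] = v[iVaDIA] * aRhoDIA * phi((d - dia) / v[iKaDIA]) -
         v[iViDIA] * phi(dia / v[iKiDIA]);
  f[2] = v[iVaROCK] * aRhoROCK * phi((r - rock) / v[iKaROCK]) -
         v[iViROCK] * phi(rock / v[iKiROCK]);
  f[3] = v[iVGEFRac] * aDIARac * aPAKRac * phi((racT - rac) / v[iKGEFRac]) -
         v[iVGAPRac] * aROCKRac * phi(rac / v[iKGAPRac]);
  f[4] = v[iVaPAK] * aRacPAK * phi((v[iP] - pak) / kaPAK) -
         v[iViPAK] * phi(pak / v[iKiPAK]);
}

// Cash-Karp tableau (stage times are not needed: the system is autonomous)
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 3.0 / 10, a42 = -9.0 / 10, a43 = 6.0 / 5;
static const double a51 = -11.0 / 54, a52 = 5.0 / 2, a53 = -70.0 / 27,
                    a54 = 35.0 / 27;
static const double a61 = 1631.0 / 55296, a62 = 175.0 / 512,
                    a63 = 575.0 / 13824, a64 = 44275.0 / 110592,
                    a65 = 253.0 / 4096;
static const double b1 = 37.0 / 378, b3 = 250.0 / 621, b4 = 125.0 / 594,
                    b6 = 512.0 / 1771;
static const double d1 = 2825.0 / 27648, d3 = 18575.0 / 48384,
                    d4 = 13525.0 / 55296, d5 = 277.0 / 14336, d6 = 1.0 / 4;

// advance one pixel's five-variable state from 0 to h_total
static bool integratePixel(double* x, const double* v, double rhoT,
                           double racT, double d, double r, double hTotal,
                           double rtol, double atol, double* hGuess) {
  double t = 0.0;
  double h = (*hGuess > 0.0 && *hGuess < hTotal) ? *hGuess : hTotal;
  const double ub[5] = { rhoT, d, r, racT, v[iP] };
  double k1[5], k2[5], k3[5], k4[5], k5[5], k6[5], xt[5], x5[5], err[5];
  int iter = 0;
  while (t < hTotal && iter++ < 100000) {
    if (t + h > hTotal) h = hTotal - t;
    rhs5(x, v, rhoT, racT, d, r, k1);
    for (int i = 0; i < 5; ++i) xt[i] = x[i] + h * a21 * k1[i];
    rhs5(xt, v, rhoT, racT, d, r, k2);
    for (int i = 0; i < 5; ++i) xt[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs5(xt, v, rhoT, racT, d, r, k3);
    for (int i = 0; i < 5; ++i)
      xt[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs5(xt, v, rhoT, racT, d, r, k4);
    for (int i = 0; i < 5; ++i)
      xt[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs5(xt, v, rhoT, racT, d, r, k5);
    for (int i = 0; i < 5; ++i)
      xt[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs5(xt, v, rhoT, racT, d, r, k6);
    double errmax = 0.0;
    for (int i = 0; i < 5; ++i) {
      x5[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b6 * k6[i]);
      double x4 = x[i] + h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] +
                              d5 * k5[i] + d6 * k6[i]);
      err[i] = std::fabs(x5[i] - x4);
      double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(x5[i]));
      errmax = std::max(errmax, err[i] / sc);
    }
    if (!std::isfinite(errmax)) return false;
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 5; ++i) {
        // clamp round-off excursions onto the admissible box
        double xi = x5[i];
        if (xi < 0.0) xi = 0.0;
        if (xi > ub[i]) xi = ub[i];
        x[i] = xi;
      }
      double fac = 0.9 * std::pow(errmax > 1e-16 ? errmax : 1e-16, -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-12) return false;
    }
  }
  *hGuess = h;
  return t >= hTotal;
}

// [[Rcpp::export(name = ".reactionStepCpp")]]
NumericMatrix reactionStepCpp(NumericMatrix S, NumericVector vpar,
                              NumericVector dloc, NumericVector rloc,
                              double hTotal, double rtol, double atol,
                              NumericVector hState) {
  const int n = S.nrow();
  if (S.ncol() != 7) stop("state matrix must have 7 columns");
  if (vpar.size() != NPAR) stop("parameter vector has wrong length");
  if (hState.size() != n) stop("step-size state has wrong length");
  NumericMatrix out(clone(S));
  const double* v = vpar.begin();
  for (int j = 0; j < n; ++j) {
    double rhoT = out(j, 0) + out(j, 1);
    double racT = out(j, 4) + out(j, 5);
    double x[5] = { out(j, 0), out(j, 2), out(j, 3), out(j, 4), out(j, 6) };
    double hg = hState[j];
    bool ok = integratePixel(x, v, rhoT, racT, dloc[j], rloc[j], hTotal,
                             rtol, atol, &hg);
    hState[j] = hg;
    if (!ok) stop("reaction step failed at pixel %d (step-size underflow "
                  "or non-finite state)", j + 1);
    out(j, 0) = x[0];
    out(j, 1) = rhoT - x[0];
    out(j, 2) = x[1];
    out(j, 3) = x[2];
    out(j, 4) = x[3];
    out(j, 5) = racT - x[3];
    out(j, 6) = x[4];
  }
  return out;
}
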