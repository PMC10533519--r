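// Pointwise ex-Gaussian log-likelihood and its first/second
// derivatives with respect to the per-trial linear predictors of the
// trajectory model. Mirrors the formulas documented in R/fit.R; the
// two-branch evaluation (direct log-Phi vs scaled complementary erf)
// matches dexgauss().

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_erfcx_pos(double y) {
  // y >= 0; branch at 25 where exp(y^2)*erfc(y) would overflow
  if (y < 25.0) {
    return y * y + std::log(std::erfc(y));
  }
  double yy = y * y;
  double corr = -0.5 / yy + 0.75 / (yy * yy) - 1.875 / (yy * yy * yy)
    + 6.5625 / (yy * yy * yy * yy);
  return -std::log(y * std::sqrt(M_PI)) + std::log1p(corr);
}

// [[Rcpp::export(name = ".iat_pieces_cpp")]]
List iat_pieces_cpp(NumericVector x, NumericVector t_idx,
                    NumericVector eta_s, NumericVector eta_r,
                    NumericVector eta_a, NumericVector eta_g,
                    double log_sigma, bool tv, bool want_grad,
                    bool want_hess) {
  const int n = x.size();
  const double sigma = std::exp(log_sigma);
  const double ln2 = M_LN2;

  NumericVector ll(n);
  NumericVector d_s(n), d_r(n), d_a(n), d_g(n), d_ls(n);
  NumericVector h_s(n), h_r(n), h_a(n), h_g(n);
  NumericVector c_sa(n), c_sr(n), c_ar(n), c_sg(n), c_ag(n), c_rg(n);

  for (int i = 0; i < n; ++i) {
    double mu = std::exp(eta_g[i]);
    double tau, g2 = 0, start = 0, asym = 0, rate = 0, L = 0;
    double dtau_s = 0, dtau_a = 0, dtau_r = 0;
    if (tv) {
      start = std::exp(eta_s[i]);
      rate = std::exp(eta_r[i]);
      asym = std::exp(eta_a[i]);
      g2 = std::pow(2.0, -(t_idx[i] - 1.0) / rate);
      tau = asym + (start - asym) * g2;
      L = ln2 * (t_idx[i] - 1.0) / rate;
    } else {
      tau = std::exp(eta_a[i]);
    }
    if (!R_finite(tau) || tau <= 0.0 || !R_finite(mu)) {
      ll[i] = R_NegInf;
      continue;
    }
    double z = (x[i] - mu) / sigma - sigma / tau;
    double lphi = R::pnorm(z, 0.0, 1.0, 1, 1);
    if (z >= 0.0) {
      ll[i] = -std::log(tau) + (mu - x[i]) / tau +
        sigma * sigma / (2.0 * tau * tau) + lphi;
    } else {
      ll[i] = -std::log(2.0 * tau) -
        (x[i] - mu) * (x[i] - mu) / (2.0 * sigma * sigma) +
        log_erfcx_pos(-z / M_SQRT2);
    }
    if (!want_grad) continue;

    double r = std::exp(R::dnorm(z, 0.0, 1.0, 1) - lphi);
    double t2 = tau * tau, t3 = t2 * tau, t4 = t3 * tau;
    double dll_dtau = -1.0 / tau - (mu - x[i]) / t2 -
      sigma * sigma / t3 + r * sigma / t2;
    double dll_dmu = 1.0 / tau - r / sigma;
    double dll_dsig = sigma / t2 +
      r * (-(x[i] - mu) / (sigma * sigma) - 1.0 / tau);

    d_g[i] = dll_dmu * mu;
    d_ls[i] = dll_dsig * sigma;
    if (tv) {
      dtau_s = g2 * start;
      dtau_a = (1.0 - g2) * asym;
      dtau_r = (start - asym) * g2 * L;
      d_s[i] = dll_dtau * dtau_s;
      d_a[i] = dll_dtau * dtau_a;
      d_r[i] = dll_dtau * dtau_r;
    } else {
      d_a[i] = dll_dtau * tau;
    }
    if (!want_hess) continue;

    double rp = -(z * r + r * r);
    double d2_dtau2 = 1.0 / t2 + 2.0 * (mu - x[i]) / t3 +
      3.0 * sigma * sigma / t4 + sigma * sigma * rp / t4 -
      2.0 * sigma * r / t3;
    double d2_dmu2 = rp / (sigma * sigma);
    double ct = -(1.0 + rp) / t2;
    h_g[i] = d2_dmu2 * mu * mu + dll_dmu * mu;
    if (tv) {
      h_s[i] = d2_dtau2 * dtau_s * dtau_s + dll_dtau * dtau_s;
      h_a[i] = d2_dtau2 * dtau_a * dtau_a + dll_dtau * dtau_a;
      h_r[i] = d2_dtau2 * dtau_r * dtau_r +
        dll_dtau * dtau_r * (L - 1.0);
      c_sa[i] = d2_dtau2 * dtau_s * dtau_a;
      c_sr[i] = d2_dtau2 * dtau_s * dtau_r + dll_dtau * dtau_s * L;
      c_ar[i] = d2_dtau2 * dtau_a * dtau_r - dll_dtau * asym * g2 * L;
      c_sg[i] = ct * mu * dtau_s;
      c_ag[i] = ct * mu * dtau_a;
      c_rg[i] = ct * mu * dtau_r;
    } else {
      h_a[i] = d2_dtau2 * tau * tau + dll_dtau * tau;
      c_ag[i] = ct * mu * tau;
    }
  }

  List out = List::create(_["ll"] = ll);
  if (want_grad) {
    out["d_s"] = d_s; out["d_r"] = d_r; out["d_a"] = d_a;
    out["d_g"] = d_g; out["d_ls"] = d_ls;
  }
  if (want_hess) {
    out["h_s"] = h_s; out["h_r"] = h_r; out["h_a"] = h_a;
    out["h_g"] = h_g;
    out["c_sa"] = c_sa; out["c_sr"] = c_sr; out["c_ar"] = c_ar;
    out["c_sg"] = c_sg; out["c_ag"] = c_ag; out["c_rg"] = c_rg;
  }
  return out;
}
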