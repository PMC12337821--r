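// Zero-inflated GHPD regression negative log-likelihood and analytic
// gradient. One evaluation per optimizer step; everything per-row is
// computed here so R-level overhead stays O(1) per call.
//
// Parameter vector layout (unconstrained scale):
//   theta = [ zero-inflation block (ncol(Zpi)) |
//             intensity block (ncol(Zlam))     |
//             family extras ]
// with logit(pi_i) = Zpi_i . thpi and, for exp-link families,
// log(lambda_i) = Zlam_i . thlam. Extras: hyper-Poisson log(psi);
// negative binomial log(size). The literal negative-binomial
// parametrization uses a logit link on the success parameter q.

#include <Rcpp.h>
using namespace Rcpp;

static const int FAM_POISSON = 0;
static const int FAM_HYPER_POISSON = 1;
static const int FAM_NEGBIN = 2; // mean-parametrized, log link
static const int FAM_NEGBIN_LITERAL = 3; // q-parametrized, logit link

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// 1F1(1; psi; lam) by series: returns log F and the scale-invariant
// ratios Fd/F (Fd = dF/dlam) and Fp/F (Fp = dF/dpsi = -sum_i t_i s_i,
// s_i = sum_{m<i} 1/(psi+m)). Accumulators are rescaled in-loop so
// large lam (terms up to ~e^lam) cannot overflow.
static inline bool hp_series(double lam, double psi, int maxTerms,
                             double &logF, double &rFd, double &rFp) {
  double t = 1.0, s = 0.0, F = 1.0, Fd = 0.0, Fp = 0.0, off = 0.0;
  for (int j = 0; j < maxTerms; j++) {
    double tn = t * lam / (psi + j);
    s += 1.0 / (psi + j);
    F += tn;
    Fd += tn * (j + 1) / lam;
    Fp -= tn * s;
    t = tn;
    if (tn < 1e-14 * F && j > 2) {
      logF = std::log(F) + off;
      rFd = Fd / F;
      rFp = Fp / F;
      return true;
    }
    if (F > 1e280) {
      const double c = 1e-280;
      t *= c; F *= c; Fd *= c; Fp *= c;
      off += std::log(1e280);
    }
  }
  return false;
}

// [[Rcpp::export]]
List zig_nll_cpp(NumericVector theta, IntegerVector x, NumericMatrix Zpi,
                 NumericMatrix Zlam, int family, double vmax, int maxTerms) {
  const int n = x.size();
  const int P = Zpi.ncol(), Q = Zlam.ncol();
  const int nextra = (family == FAM_POISSON) ? 0 : 1;
  if (theta.size() != P + Q + nextra)
    stop("theta has length %d, expected %d", theta.size(), P + Q + nextra);

  std::vector<double> u(n), v(n);
  for (int i = 0; i < n; i++) {
    double ui = 0.0, vi = 0.0;
    for (int j = 0; j < P; j++) ui += Zpi(i, j) * theta[j];
    for (int j = 0; j < Q; j++) vi += Zlam(i, j) * theta[P + j];
    u[i] = ui; v[i] = vi;
  }

  // soft barrier keeping the intensity predictor in series-safe range
  double pen = 0.0;
  std::vector<double> pgrad_v(n, 0.0);
  bool out_of_range = false;
  for (int i = 0; i < n; i++) {
    double ex = v[i] - vmax;
    if (ex > 0.0) {
      out_of_range = true;
      pen += ex * ex;
      pgrad_v[i] = 2.0 * ex;
    }
  }
  NumericVector grad(P + Q + nextra);
  if (out_of_range) {
    for (int j = 0; j < Q; j++) {
      double g = 0.0;
      for (int i = 0; i < n; i++) g += Zlam(i, j) * pgrad_v[i];
      grad[P + j] = 1e4 * g;
    }
    return List::create(_["value"] = 1e8 + 1e4 * pen, _["gradient"] = grad);
  }

  double extra = (nextra > 0) ? theta[P + Q] : 0.0; // log psi / log size
  double psi = std::exp(extra);

  double nll = 0.0, g_extra = 0.0;
  std::vector<double> w_u(n), w_v(n);
  double dig_psi = (family == FAM_HYPER_POISSON || family == FAM_NEGBIN ||
                    family == FAM_NEGBIN_LITERAL) ? R::digamma(psi) : 0.0;

  for (int i = 0; i < n; i++) {
    const int xi = x[i];
    const double ui = u[i], vi = v[i];
    const double pii = 1.0 / (1.0 + std::exp(-ui));
    double lp, dlp_dv, dlp_de = 0.0;   // log GHP pmf at xi and derivatives
    double lp0, dlp0_dv, dlp0_de = 0.0; // same at 0 (only used when xi == 0)

    if (family == FAM_POISSON) {
      double lam = std::exp(vi);
      if (xi == 0) {
        lp0 = -lam; dlp0_dv = -lam;
        lp = lp0; dlp_dv = dlp0_dv;
      } else {
        lp = xi * vi - lam - R::lgammafn(xi + 1.0);
        dlp_dv = xi - lam;
        lp0 = 0.0; dlp0_dv = 0.0;
      }
    } else if (family == FAM_HYPER_POISSON) {
      double lam = std::exp(vi);
      double logF, rFd, rFp;
      if (!hp_series(lam, psi, maxTerms, logF, rFd, rFp))
        stop("hyper-Poisson series did not converge within %d terms "
             "(lambda = %g)", maxTerms, lam);
      double dlogF_dv = lam * rFd;
      double dlogF_de = psi * rFp;
      lp0 = -logF; dlp0_dv = -dlogF_dv; dlp0_de = -dlogF_de;
      if (xi == 0) {
        lp = lp0; dlp_dv = dlp0_dv; dlp_de = dlp0_de;
      } else {
        lp = xi * vi - (R::lgammafn(psi + xi) - R::lgammafn(psi)) - logF;
        dlp_dv = xi - dlogF_dv;
        dlp_de = psi * (-(R::digamma(psi + xi) - dig_psi)) - dlogF_de;
      }
    } else if (family == FAM_NEGBIN) {
      double m = std::exp(vi), k = psi;
      double lmk = std::log(m + k);
      lp0 = k * (std::log(k) - lmk);
      dlp0_dv = -k * m / (m + k);
      dlp0_de = k * (std::log(k) - lmk + 1.0 - k / (m + k));
      if (xi == 0) {
        lp = lp0; dlp_dv = dlp0_dv; dlp_de = dlp0_de;
      } else {
        lp = R::lgammafn(xi + k) - R::lgammafn(k) - R::lgammafn(xi + 1.0)
             + xi * (vi - lmk) + k * (std::log(k) - lmk);
        dlp_dv = xi - (xi + k) * m / (m + k);
        dlp_de = k * (R::digamma(xi + k) - dig_psi + std::log(k) - lmk
                      + 1.0 - (xi + k) / (m + k));
      }
    } else { // FAM_NEGBIN_LITERAL
      double q = 1.0 / (1.0 + std::exp(-vi)), k = psi;
      double l1q = -softplus(vi); // log(1 - q)
      lp0 = k * l1q;
      dlp0_dv = -k * q;
      dlp0_de = k * l1q;
      if (xi == 0) {
        lp = lp0; dlp_dv = dlp0_dv; dlp_de = dlp0_de;
      } else {
        lp = R::lgammafn(xi + k) - R::lgammafn(k) - R::lgammafn(xi + 1.0)
             + xi * std::log(q) + k * l1q;
        dlp_dv = xi * (1.0 - q) - k * q;
        dlp_de = k * (R::digamma(xi + k) - dig_psi + l1q);
      }
    }

    if (xi == 0) {
      // ll = log(pi + (1 - pi) p0), numerically as a function of u and lp0
      double p0 = std::exp(lp0);
      double logA;
      if (ui > 0)
        logA = ui + std::log1p(p0 * std::exp(-ui)) - softplus(ui);
      else
        logA = std::log(std::exp(ui) + p0) - softplus(ui);
      nll -= logA;
      double A = pii + (1.0 - pii) * p0;
      w_u[i] = pii * (1.0 - pii) * (1.0 - p0) / A;
      double wz = (1.0 - pii) * p0 / A;
      w_v[i] = wz * dlp0_dv;
      g_extra += wz * dlp0_de;
    } else {
      nll -= (-softplus(ui)) + lp; // log(1 - pi) + log pmf
      w_u[i] = -pii;
      w_v[i] = dlp_dv;
      g_extra += dlp_de;
    }
  }

  for (int j = 0; j < P; j++) {
    double g = 0.0;
    for (int i = 0; i < n; i++) g += Zpi(i, j) * w_u[i];
    grad[j] = -g;
  }
  for (int j = 0; j < Q; j++) {
    double g = 0.0;
    for (int i = 0; i < n; i++) g += Zlam(i, j) * w_v[i];
    grad[P + j] = -g;
  }
  if (nextra > 0) grad[P + Q] = -g_extra;

  return List::create(_["value"] = nll, _["gradient"] = grad);
}

// Vectorized 1F1(1; psi; lam) over a vector of lam (shared psi);
// used by the forward sampler.
// [[Rcpp::export]]
NumericVector hp_norm_cpp(NumericVector lam, double psi, int maxTerms) {
  const int n = lam.size();
  NumericVector F(n);
  for (int i = 0; i < n; i++) {
    double logF, rFd, rFp;
    if (!hp_series(lam[i], psi, maxTerms, logF, rFd, rFp))
      stop("series did not converge within %d terms", maxTerms);
    F[i] = std::exp(logF);
  }
  return F;
}
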