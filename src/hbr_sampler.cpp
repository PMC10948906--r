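// Adaptive Hamiltonian Monte Carlo for the hierarchical SHASHb
// normative regression.
//
// Model (per ROI, responses and age standardized in R):
//   y_i ~ SHASHb(mu_i, sigma_{b(i)}, eps, delta)
//   mu_i = X_i . coef[b(i), ]          (X includes the intercept column)
//   sigma_b = softplus(s_b)
//   coef[b,k] ~ N(mu_k, tau_k^2),  s_b ~ N(mu_s, tau_s^2)   (partial pooling)
//   mu_k, mu_s ~ N(0,1); tau ~ Half-Normal(1) sampled on the log scale;
//   eps ~ N(0,1); delta = softplus(d0 + delta_raw), delta_raw ~ N(0,1),
//   d0 = log(e-1) so delta_raw = 0 gives delta = 1 (Gaussian tails).
//
// Unconstrained parameter vector theta (K basis columns, B batch cells):
//   [ mu_coef(K) | log_tau_coef(K) | mu_s | log_tau_s |
//     zc(B*K, b-major) | zs(B) | eps | delta_raw ]
// Non-centered: coef[b,k] = mu_k + tau_k * zc[b,k], s_b = mu_s + tau_s*zs[b].
// Centered:     zc holds coef directly, zs holds s_b directly.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 30.0 ? x : log1p(exp(x));
}
static inline double sigmoid(double x) { return 1.0 / (1.0 + exp(-x)); }
static inline double logcosh(double t) {
  double a = fabs(t);
  return a + log1p(exp(-2.0 * a)) - M_LN2;
}

// mean and variance of the base sinh-arcsinh variate
static void shash_mv(double eps, double delta, double &m, double &v) {
  const double c0 = exp(0.25) / sqrt(8.0 * M_PI);
  double q1 = 1.0 / delta, q2 = 2.0 / delta;
  double P1 = c0 * (R::bessel_k(0.25, (q1 + 1.0) / 2.0, 1.0) +
                    R::bessel_k(0.25, fabs(q1 - 1.0) / 2.0, 1.0));
  double P2 = c0 * (R::bessel_k(0.25, (q2 + 1.0) / 2.0, 1.0) +
                    R::bessel_k(0.25, fabs(q2 - 1.0) / 2.0, 1.0));
  m = sinh(eps / delta) * P1;
  v = 0.5 * (cosh(2.0 * eps / delta) * P2 - 1.0) - m * m;
}

// central finite differences of (m, v) in (eps, delta); cheap, data-free
static void shash_mv_grad(double eps, double delta, double &m, double &v,
                          double &dm_de, double &dv_de,
                          double &dm_dd, double &dv_dd) {
  shash_mv(eps, delta, m, v);
  const double he = 1e-6, hd = 1e-6 * std::max(1.0, delta);
  double mp, vp, mm, vm;
  shash_mv(eps + he, delta, mp, vp);
  shash_mv(eps - he, delta, mm, vm);
  dm_de = (mp - mm) / (2 * he);
  dv_de = (vp - vm) / (2 * he);
  shash_mv(eps, delta + hd, mp, vp);
  shash_mv(eps, delta - hd, mm, vm);
  dm_dd = (mp - mm) / (2 * hd);
  dv_dd = (vp - vm) / (2 * hd);
}

struct HBRData {
  const double *y;
  const double *X;   // n x K, column-major
  const int *cell;   // 0-based
  int n, K, B;
  bool centered;
  int dim() const { return 2 * K + 2 + B * K + B + 2; }
};

// log posterior and gradient; returns -inf on numerical failure
static double logpost_grad(const HBRData &d, const double *th, double *g) {
  const int K = d.K, B = d.B, n = d.n;
  const double d0 = log(M_E - 1.0);
  const int i_mu = 0, i_lt = K, i_ms = 2 * K, i_lts = 2 * K + 1,
            i_zc = 2 * K + 2, i_zs = i_zc + B * K, i_eps = i_zs + B,
            i_dr = i_eps + 1;
  const int dim = d.dim();
  for (int j = 0; j < dim; ++j) g[j] = 0.0;

  std::vector<double> tau(K), coef(B * K), sb(B), sigb(B);
  for (int k = 0; k < K; ++k) tau[k] = exp(th[i_lt + k]);
  double tau_s = exp(th[i_lts]);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      double z = th[i_zc + b * K + k];
      coef[b * K + k] = d.centered ? z : th[i_mu + k] + tau[k] * z;
    }
    double zs = th[i_zs + b];
    sb[b] = d.centered ? zs : th[i_ms] + tau_s * zs;
    sigb[b] = softplus(sb[b]);
    if (!(sigb[b] > 0) || !std::isfinite(sigb[b])) return R_NegInf;
  }
  double eps = th[i_eps];
  double delta = softplus(d0 + th[i_dr]);
  // tiny delta blows up the Bessel order (2/delta) in the moment
  // functions; treat such proposals as divergent
  if (!(delta > 1e-3) || !std::isfinite(delta) || delta > 1e3)
    return R_NegInf;

  double m, v, dm_de, dv_de, dm_dd, dv_dd;
  shash_mv_grad(eps, delta, m, v, dm_de, dv_de, dm_dd, dv_dd);
  if (!(v > 0) || !std::isfinite(v)) return R_NegInf;
  double kv = sqrt(v);

  std::vector<double> g_coef(B * K, 0.0), g_sig(B, 0.0);
  double g_eps = 0.0, g_del = 0.0, lp = 0.0;
  const double l2pi = 0.5 * log(2.0 * M_PI);

  for (int i = 0; i < n; ++i) {
    int b = d.cell[i];
    double mu_i = 0.0;
    for (int k = 0; k < K; ++k) mu_i += d.X[k * n + i] * coef[b * K + k];
    double sig = sigb[b];
    double resid = (d.y[i] - mu_i) / sig;
    double s = resid * kv + m;
    double q2 = 1.0 + s * s;
    double a = asinh(s);
    double t = delta * a - eps;
    if (fabs(t) > 300.0) return R_NegInf;  // sinh overflow => divergence
    double r = sinh(t), c = cosh(t);
    lp += log(delta) + logcosh(t) - l2pi - 0.5 * log(q2) - 0.5 * r * r +
          0.5 * log(v) - log(sig);
    double rc = r * c, roc = r / c;
    double dl_ds = delta / sqrt(q2) * (roc - rc) - s / q2;
    double dl_dmu = dl_ds * (-kv / sig);
    double dl_dsig = dl_ds * (-resid * kv / sig) - 1.0 / sig;
    double ds_de = dm_de + resid * dv_de / (2.0 * kv);
    double ds_dd = dm_dd + resid * dv_dd / (2.0 * kv);
    g_eps += (rc - roc) + dl_ds * ds_de + 0.5 * dv_de / v;
    g_del += 1.0 / delta + a * (roc - rc) + dl_ds * ds_dd + 0.5 * dv_dd / v;
    for (int k = 0; k < K; ++k)
      g_coef[b * K + k] += dl_dmu * d.X[k * n + i];
    g_sig[b] += dl_dsig;
  }
  if (!std::isfinite(lp)) return R_NegInf;

  // chain rule: likelihood contributions into theta space
  for (int b = 0; b < B; ++b) {
    double g_sb = g_sig[b] * sigmoid(sb[b]);  // d softplus
    if (d.centered) {
      for (int k = 0; k < K; ++k) g[i_zc + b * K + k] += g_coef[b * K + k];
      g[i_zs + b] += g_sb;
    } else {
      for (int k = 0; k < K; ++k) {
        double gc = g_coef[b * K + k];
        g[i_mu + k] += gc;
        g[i_lt + k] += gc * th[i_zc + b * K + k] * tau[k];
        g[i_zc + b * K + k] += gc * tau[k];
      }
      g[i_ms] += g_sb;
      g[i_lts] += g_sb * th[i_zs + b] * tau_s;
      g[i_zs + b] += g_sb * tau_s;
    }
  }
  g[i_eps] += g_eps;
  g[i_dr] += g_del * sigmoid(d0 + th[i_dr]);

  // priors
  for (int k = 0; k < K; ++k) {
    lp += -0.5 * th[i_mu + k] * th[i_mu + k];
    g[i_mu + k] += -th[i_mu + k];
    lp += -0.5 * tau[k] * tau[k] + th[i_lt + k];  // half-normal + Jacobian
    g[i_lt + k] += -tau[k] * tau[k] + 1.0;
  }
  lp += -0.5 * th[i_ms] * th[i_ms];
  g[i_ms] += -th[i_ms];
  lp += -0.5 * tau_s * tau_s + th[i_lts];
  g[i_lts] += -tau_s * tau_s + 1.0;
  if (d.centered) {
    for (int b = 0; b < B; ++b) {
      for (int k = 0; k < K; ++k) {
        double dev = (coef[b * K + k] - th[i_mu + k]) / tau[k];
        lp += -0.5 * dev * dev - th[i_lt + k];
        g[i_zc + b * K + k] += -dev / tau[k];
        g[i_mu + k] += dev / tau[k];
        g[i_lt + k] += dev * dev - 1.0;
      }
      double devs = (sb[b] - th[i_ms]) / tau_s;
      lp += -0.5 * devs * devs - th[i_lts];
      g[i_zs + b] += -devs / tau_s;
      g[i_ms] += devs / tau_s;
      g[i_lts] += devs * devs - 1.0;
    }
  } else {
    for (int b = 0; b < B; ++b) {
      for (int k = 0; k < K; ++k) {
        double z = th[i_zc + b * K + k];
        lp += -0.5 * z * z;
        g[i_zc + b * K + k] += -z;
      }
      double zs = th[i_zs + b];
      lp += -0.5 * zs * zs;
      g[i_zs + b] += -zs;
    }
  }
  lp += -0.5 * eps * eps;
  g[i_eps] += -eps;
  lp += -0.5 * th[i_dr] * th[i_dr];
  g[i_dr] += -th[i_dr];
  return lp;
}

// [[Rcpp::export(name = ".hbr_logpost_grad")]]
List hbr_logpost_grad(NumericVector theta, NumericVector y,
                      NumericMatrix X, IntegerVector cell, int B,
                      bool centered) {
  HBRData d;
  d.y = y.begin(); d.X = X.begin(); d.cell = cell.begin();
  d.n = y.size(); d.K = X.ncol(); d.B = B; d.centered = centered;
  NumericVector g(d.dim());
  double lp = logpost_grad(d, theta.begin(), g.begin());
  return List::create(_["logpost"] = lp, _["grad"] = g);
}

struct Leapfrog {
  const HBRData *d;
  std::vector<double> inv_mass;
  // one trajectory; returns accept probability, updates th on acceptance
  // diverged set when the Hamiltonian blows up
  bool diverged;
  double run(std::vector<double> &th, double eps_step, int n_steps,
             double &lp0, std::vector<double> &grad0, bool &accepted) {
    int dim = d->dim();
    std::vector<double> p(dim), th_new(th), g(grad0);
    double kin0 = 0.0;
    for (int j = 0; j < dim; ++j) {
      p[j] = norm_rand() / sqrt(inv_mass[j]);
      kin0 += 0.5 * p[j] * p[j] * inv_mass[j];
    }
    double H0 = -lp0 + kin0;
    double lp = lp0;
    diverged = false;
    for (int s = 0; s < n_steps; ++s) {
      for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps_step * g[j];
      for (int j = 0; j < dim; ++j)
        th_new[j] += eps_step * p[j] * inv_mass[j];
      lp = logpost_grad(*d, th_new.data(), g.data());
      if (!std::isfinite(lp)) { diverged = true; break; }
      for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps_step * g[j];
      double kin = 0.0;
      for (int j = 0; j < dim; ++j) kin += 0.5 * p[j] * p[j] * inv_mass[j];
      if (-lp + kin - H0 > 1000.0) { diverged = true; break; }
    }
    double a = 0.0;
    accepted = false;
    if (!diverged) {
      double kin = 0.0;
      for (int j = 0; j < dim; ++j) kin += 0.5 * p[j] * p[j] * inv_mass[j];
      double H1 = -lp + kin;
      a = std::min(1.0, exp(H0 - H1));
      if (unif_rand() < a) {
        th = th_new;
        grad0 = g;
        lp0 = lp;
        accepted = true;
      }
    }
    return a;
  }
};

// Hoffman-Gelman heuristic for a reasonable step size under the
// current (diagonal) metric: double/halve until the one-step
// acceptance probability crosses 1/2
static double find_epsilon(const HBRData &d, const std::vector<double> &th,
                           const std::vector<double> &inv_mass) {
  int dim = d.dim();
  std::vector<double> g0(dim), g(dim), p(dim), thn(dim);
  double lp0 = logpost_grad(d, th.data(), g0.data());
  double eps = 0.1;
  int dir = 0;
  for (int tries = 0; tries < 40; ++tries) {
    for (int j = 0; j < dim; ++j) p[j] = norm_rand() / sqrt(inv_mass[j]);
    double kin0 = 0.0;
    for (int j = 0; j < dim; ++j) kin0 += 0.5 * p[j] * p[j] * inv_mass[j];
    thn = th; g = g0;
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * g[j];
    for (int j = 0; j < dim; ++j) thn[j] += eps * p[j] * inv_mass[j];
    double lp = logpost_grad(d, thn.data(), g.data());
    double log_a;
    if (!std::isfinite(lp)) log_a = -1e10;
    else {
      for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * g[j];
      double kin = 0.0;
      for (int j = 0; j < dim; ++j) kin += 0.5 * p[j] * p[j] * inv_mass[j];
      log_a = (lp - kin) - (lp0 - kin0);
    }
    int want = log_a > log(0.5) ? 1 : -1;
    if (dir == 0) dir = want;
    if (want != dir) break;  // crossed the target: stop
    eps *= (dir == 1) ? 2.0 : 0.5;
    if (eps > 4.0 || eps < 1e-7) break;
  }
  return std::min(eps, 2.0);
}

// [[Rcpp::export(name = ".hbr_sample")]]
List hbr_sample(NumericVector y, NumericMatrix X, IntegerVector cell,
                int B, int n_chains, int n_iter, int n_warm,
                double target_accept, bool centered, double traj_len,
                int max_steps, double init_jitter) {
  HBRData d;
  d.y = y.begin(); d.X = X.begin(); d.cell = cell.begin();
  d.n = y.size(); d.K = X.ncol(); d.B = B; d.centered = centered;
  const int dim = d.dim();
  const int n_keep = n_iter - n_warm;
  if (n_keep <= 0) stop("n_iter must exceed n_warm");

  NumericVector draws(Dimension(n_keep, dim, n_chains));
  NumericVector accept_rate(n_chains), step_size(n_chains);
  IntegerVector divergences(n_chains);

  for (int ch = 0; ch < n_chains; ++ch) {
    std::vector<double> th(dim);
    for (int j = 0; j < dim; ++j) th[j] = init_jitter * norm_rand();
    Leapfrog lf;
    lf.d = &d;
    lf.inv_mass.assign(dim, 1.0);
    std::vector<double> g(dim);
    double lp = logpost_grad(d, th.data(), g.data());
    int guard = 0;
    while (!std::isfinite(lp) && guard++ < 100) {
      for (int j = 0; j < dim; ++j) th[j] = init_jitter * norm_rand();
      lp = logpost_grad(d, th.data(), g.data());
    }
    if (!std::isfinite(lp)) stop("could not find a finite starting point");

    double eps_step = find_epsilon(d, th, lf.inv_mass);
    // dual averaging state
    double mu_da = log(10.0 * eps_step), log_eps = log(eps_step),
           log_eps_bar = 0.0, Hbar = 0.0;
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    int da_count = 0;
    // variance-collection window for the diagonal mass matrix
    int w_lo = (int)(0.25 * n_warm), w_hi = (int)(0.75 * n_warm);
    std::vector<double> acc1(dim, 0.0), acc2(dim, 0.0);
    int w_n = 0;

    double acc_sum = 0.0;
    int n_div = 0;
    for (int it = 0; it < n_iter; ++it) {
      bool warm = it < n_warm;
      double cur_eps = warm ? exp(log_eps) : eps_step;
      int L = (int)(traj_len / cur_eps + 0.5);
      if (L < 1) L = 1;
      if (L > max_steps) L = max_steps;
      int steps = 1 + (int)(unif_rand() * L);
      bool accepted;
      double a = lf.run(th, cur_eps, steps, lp, g, accepted);
      if (warm) {
        ++da_count;
        Hbar = (1.0 - 1.0 / (da_count + t0)) * Hbar +
               (target_accept - a) / (da_count + t0);
        log_eps = mu_da - sqrt((double)da_count) / gamma * Hbar;
        double w = pow((double)da_count, -kappa);
        log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
        if (it >= w_lo && it < w_hi) {
          for (int j = 0; j < dim; ++j) {
            acc1[j] += th[j];
            acc2[j] += th[j] * th[j];
          }
          ++w_n;
        }
        if (it == w_hi - 1 && w_n > 10) {
          // regularized variance estimate (shrunk toward unit mass),
          // as in Stan's windowed adaptation
          for (int j = 0; j < dim; ++j) {
            double mean = acc1[j] / w_n;
            double var = acc2[j] / w_n - mean * mean;
            var = var * w_n / (w_n + 5.0) + 1e-3 * 5.0 / (w_n + 5.0);
            lf.inv_mass[j] = std::max(var, 1e-8);
          }
          // re-find a reasonable step size under the new metric and
          // restart dual averaging around it
          double e = find_epsilon(d, th, lf.inv_mass);
          mu_da = log(10.0 * e);
          log_eps = log(e);
          log_eps_bar = log(e);
          Hbar = 0.0;
          da_count = 0;
        }
        if (it == n_warm - 1) eps_step = exp(log_eps_bar);
      } else {
        acc_sum += a;
        if (lf.diverged) ++n_div;
        int kk = it - n_warm;
        for (int j = 0; j < dim; ++j)
          draws[kk + n_keep * (j + dim * ch)] = th[j];
      }
    }
    accept_rate[ch] = acc_sum / n_keep;
    step_size[ch] = eps_step;
    divergences[ch] = n_div;
  }
  return List::create(_["draws"] = draws, _["accept_rate"] = accept_rate,
                      _["step_size"] = step_size,
                      _["divergences"] = divergences);
}
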