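// Hamiltonian Monte Carlo for the cumulative and stereotype ordinal models.
//
// The posterior is sampled on an unconstrained scale:
//   cumulative: theta = [alpha_1, log-increments (C-2), delta (K), beta (J*K), log-tau (K)]
//   stereotype: theta = [alpha_2..alpha_C (C-1), z (C-2), delta (K), beta (J*K), log-tau (K)]
// where the stereotype simplex gamma = softmax(c(z, 0)) and phi = c(0, cumsum(gamma)).
// beta is present only for heterogeneous models, log-tau only when the
// heterogeneity scale is learned (default keeps it fixed at sqrt(sigma2)).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// log(1/(1+exp(-u))), stable on both tails
static inline double log_sigmoid(double u) {
  return u >= 0.0 ? -std::log1p(std::exp(-u)) : u - std::log1p(std::exp(u));
}
static inline double sigmoid(double u) {
  return u >= 0.0 ? 1.0 / (1.0 + std::exp(-u)) : std::exp(u) / (1.0 + std::exp(u));
}
// log(1 - exp(x)) for x <= 0
static inline double log1m_exp(double x) {
  if (x >= 0.0) return R_NegInf;
  return x > -M_LN2 ? std::log(-std::expm1(x)) : std::log1p(-std::exp(x));
}

struct Model {
  int N, J, K, C, family;          // family: 0 cumulative, 1 stereotype
  bool het, prior_only, learn_tau;
  const int *y, *pid;              // y in 1..C, pid 0-based
  const double *X;                 // row-major N x K
  const double *mu;                // prior means for delta, length K
  double sigma2, dirA, tau0sd;

  int offset_delta() const { return family == 0 ? (C - 1) : (2 * C - 3); }
  int offset_beta()  const { return offset_delta() + K; }
  int offset_tau()   const { return offset_beta() + (het ? J * K : 0); }
  int dim() const {
    return offset_delta() + K + (het ? J * K : 0) + ((het && learn_tau) ? K : 0);
  }

  // log posterior density (up to additive constants) and its gradient
  double logpost_grad(const double *th, double *g) const {
    const int D = dim();
    std::fill(g, g + D, 0.0);
    double lp = 0.0;
    const int od = offset_delta(), ob = offset_beta(), ot = offset_tau();
    const double *del = th + od;

    std::vector<double> alpha(C), ga(C, 0.0);
    std::vector<double> gamma, phi, gphi;
    const int nz = C - 2;

    if (family == 0) {
      alpha[0] = th[0];
      for (int c = 1; c < C - 1; ++c) alpha[c] = alpha[c - 1] + std::exp(th[c]);
      for (int c = 0; c < C - 1; ++c) {
        lp += -0.5 * alpha[c] * alpha[c] / sigma2;
        ga[c] += -alpha[c] / sigma2;
      }
      for (int c = 1; c < C - 1; ++c) { lp += th[c]; g[c] += 1.0; }  // Jacobian
    } else {
      alpha[0] = 0.0;
      for (int c = 1; c < C; ++c) alpha[c] = th[c - 1];
      for (int c = 1; c < C; ++c) {
        lp += -0.5 * alpha[c] * alpha[c] / sigma2;
        ga[c] += -alpha[c] / sigma2;
      }
      // gamma = softmax(z, 0); Dirichlet(A) kernel + ALR Jacobian = A * sum(log gamma)
      gamma.assign(C - 1, 0.0);
      double mx = 0.0;
      for (int i = 0; i < nz; ++i) mx = std::max(mx, th[C - 1 + i]);
      double s = 0.0;
      for (int i = 0; i < C - 1; ++i) {
        double wi = (i < nz) ? th[C - 1 + i] : 0.0;
        gamma[i] = std::exp(wi - mx);
        s += gamma[i];
      }
      for (int i = 0; i < C - 1; ++i) gamma[i] /= s;
      phi.assign(C, 0.0);
      for (int c = 1; c < C; ++c) phi[c] = phi[c - 1] + gamma[c - 1];
      phi[C - 1] = 1.0;
      for (int i = 0; i < C - 1; ++i)
        lp += dirA * std::log(std::max(gamma[i], 1e-300));
      gphi.assign(C, 0.0);
    }

    for (int k = 0; k < K; ++k) {
      double r = del[k] - mu[k];
      lp += -0.5 * r * r / sigma2;
      g[od + k] += -r / sigma2;
    }

    std::vector<double> tau2(K, sigma2);
    if (het && learn_tau) {
      for (int k = 0; k < K; ++k) {
        double lt = th[ot + k], t = std::exp(lt);
        tau2[k] = t * t;
        // half-normal(0, tau0sd) on tau, plus log-Jacobian of t = exp(lt)
        lp += -0.5 * t * t / (tau0sd * tau0sd) + lt;
        g[ot + k] += -t * t / (tau0sd * tau0sd) + 1.0;
      }
    }
    if (het) {
      for (int j = 0; j < J; ++j) {
        for (int k = 0; k < K; ++k) {
          double b = th[ob + j * K + k];
          double r = b - del[k];
          lp += -0.5 * r * r / tau2[k];
          g[ob + j * K + k] += -r / tau2[k];
          g[od + k] += r / tau2[k];
          if (learn_tau) {
            lp += -th[ot + k];
            g[ot + k] += r * r / tau2[k] - 1.0;
          }
        }
      }
    }

    if (!prior_only) {
      std::vector<double> sc(C), pr(C);
      for (int i = 0; i < N; ++i) {
        const int j = het ? pid[i] : 0;
        const double *bet = het ? (th + ob + j * K) : del;
        const double *xi = X + (size_t)i * K;
        double eta = 0.0;
        for (int k = 0; k < K; ++k) eta += xi[k] * bet[k];
        const int yi = y[i];
        double deta = 0.0;

        if (family == 0) {
          if (yi == 1) {
            double u = alpha[0] - eta;
            lp += log_sigmoid(u);
            double d = 1.0 - sigmoid(u);
            ga[0] += d; deta = -d;
          } else if (yi == C) {
            double u = alpha[C - 2] - eta;
            lp += log_sigmoid(-u);
            double d = -sigmoid(u);
            ga[C - 2] += d; deta = -d;
          } else {
            double b = alpha[yi - 1] - eta, a = alpha[yi - 2] - eta;
            double lFb = log_sigmoid(b), lFa = log_sigmoid(a);
            double logp = lFb + log1m_exp(lFa - lFb);
            if (!std::isfinite(logp)) logp = -745.0;
            lp += logp;
            // f(u) = F(u)(1-F(u)); ratios computed in logs to avoid overflow
            double lfb = lFb + log_sigmoid(-b), lfa = lFa + log_sigmoid(-a);
            double dldb = std::exp(std::min(lfb - logp, 27.6));
            double dlda = -std::exp(std::min(lfa - logp, 27.6));
            ga[yi - 1] += dldb; ga[yi - 2] += dlda;
            deta = -(dldb + dlda);
          }
        } else {
          double mx = -1e308;
          for (int c = 0; c < C; ++c) {
            sc[c] = alpha[c] + phi[c] * eta;
            if (sc[c] > mx) mx = sc[c];
          }
          double s = 0.0;
          for (int c = 0; c < C; ++c) { pr[c] = std::exp(sc[c] - mx); s += pr[c]; }
          lp += sc[yi - 1] - mx - std::log(s);
          for (int c = 0; c < C; ++c) {
            double r = ((c == yi - 1) ? 1.0 : 0.0) - pr[c] / s;
            if (c >= 1) ga[c] += r;
            if (c >= 1 && c <= C - 2) gphi[c] += eta * r;
            deta += phi[c] * r;
          }
        }

        if (het) {
          double *gb = g + ob + j * K;
          for (int k = 0; k < K; ++k) gb[k] += deta * xi[k];
        } else {
          for (int k = 0; k < K; ++k) g[od + k] += deta * xi[k];
        }
      }
    }

    // pull cutpoint/score gradients back to the unconstrained scale
    if (family == 0) {
      std::vector<double> suf(C - 1);
      double acc = 0.0;
      for (int c = C - 2; c >= 0; --c) { acc += ga[c]; suf[c] = acc; }
      g[0] += suf[0];
      for (int c = 1; c < C - 1; ++c) g[c] += std::exp(th[c]) * suf[c];
    } else {
      for (int c = 1; c < C; ++c) g[c - 1] += ga[c];
      std::vector<double> ggam(C - 1, 0.0);
      for (int m = C - 2; m >= 0; --m)
        ggam[m] = ((m + 1 <= C - 2) ? gphi[m + 1] : 0.0) +
                  ((m + 1 <= C - 2) ? ggam[m + 1] : 0.0);
      double dot = 0.0;
      for (int m = 0; m < C - 1; ++m) dot += gamma[m] * ggam[m];
      for (int i = 0; i < nz; ++i)
        g[C - 1 + i] += gamma[i] * (ggam[i] - dot) +
                        dirA * (1.0 - (C - 1) * gamma[i]);
    }
    return lp;
  }
};

static Model make_model(const IntegerVector &y, const NumericMatrix &X,
                        const IntegerVector &pid0, int J, int C, int family,
                        bool heterogeneous, bool prior_only, bool learn_tau,
                        const NumericVector &prior_mu, double sigma2,
                        double dirichlet_a, double tau0sd,
                        std::vector<double> &Xrow) {
  const int N = X.nrow(), K = X.ncol();
  Xrow.resize((size_t)N * K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Xrow[(size_t)i * K + k] = X(i, k);
  Model m;
  m.N = N; m.J = J; m.K = K; m.C = C; m.family = family;
  m.het = heterogeneous; m.prior_only = prior_only; m.learn_tau = learn_tau;
  m.y = y.begin(); m.pid = pid0.begin(); m.X = Xrow.data();
  m.mu = prior_mu.begin(); m.sigma2 = sigma2; m.dirA = dirichlet_a;
  m.tau0sd = tau0sd;
  return m;
}

// [[Rcpp::export(name = ".hmc_logpost")]]
List hmc_logpost(NumericVector theta, IntegerVector y, NumericMatrix X,
                 IntegerVector pid0, int J, int C, int family,
                 bool heterogeneous, bool prior_only, bool learn_tau,
                 NumericVector prior_mu, double sigma2, double dirichlet_a,
                 double tau0sd) {
  std::vector<double> Xrow;
  Model m = make_model(y, X, pid0, J, C, family, heterogeneous, prior_only,
                       learn_tau, prior_mu, sigma2, dirichlet_a, tau0sd, Xrow);
  if ((int)theta.size() != m.dim()) stop("theta has wrong length");
  NumericVector g(m.dim());
  double lp = m.logpost_grad(theta.begin(), g.begin());
  return List::create(_["log_posterior"] = lp, _["gradient"] = g);
}

// [[Rcpp::export(name = ".hmc_run_chain")]]
List hmc_run_chain(IntegerVector y, NumericMatrix X, IntegerVector pid0,
                   int J, int C, int family, bool heterogeneous,
                   bool prior_only, bool learn_tau, NumericVector prior_mu,
                   double sigma2, double dirichlet_a, double tau0sd,
                   int iter, int warmup, int thin, NumericVector init,
                   double target_accept, int max_leapfrog) {
  std::vector<double> Xrow;
  Model m = make_model(y, X, pid0, J, C, family, heterogeneous, prior_only,
                       learn_tau, prior_mu, sigma2, dirichlet_a, tau0sd, Xrow);
  const int D = m.dim();
  if ((int)init.size() != D) stop("init has wrong length (expected %d)", D);

  std::vector<double> th(init.begin(), init.end());
  std::vector<double> g(D), gp(D), thp(D), mom(D), minv(D, 1.0);
  double lp = m.logpost_grad(th.data(), g.data());
  if (!std::isfinite(lp)) stop("non-finite log posterior at initial values");

  // heuristic initial step size: double/halve until one leapfrog step has
  // acceptance probability crossing 1/2 (Hoffman & Gelman style)
  double eps = 0.1;
  {
    auto delta_h = [&](double e) {
      std::vector<double> p(D), t2(th), g2(g);
      double ke0 = 0.0;
      for (int d = 0; d < D; ++d) { p[d] = norm_rand(); ke0 += 0.5 * p[d] * p[d]; }
      for (int d = 0; d < D; ++d) p[d] += 0.5 * e * g2[d];
      for (int d = 0; d < D; ++d) t2[d] += e * p[d];
      double lp2 = m.logpost_grad(t2.data(), g2.data());
      if (!std::isfinite(lp2)) return -1e300;
      for (int d = 0; d < D; ++d) p[d] += 0.5 * e * g2[d];
      double ke1 = 0.0;
      for (int d = 0; d < D; ++d) ke1 += 0.5 * p[d] * p[d];
      return (lp2 - ke1) - (lp - ke0);
    };
    double dh = delta_h(eps);
    double dir = (dh > std::log(0.5)) ? 1.0 : -1.0;
    for (int tries = 0; tries < 60; ++tries) {
      eps *= (dir > 0 ? 2.0 : 0.5);
      dh = delta_h(eps);
      if ((dir > 0 && dh <= std::log(0.5)) || (dir < 0 && dh >= std::log(0.5)))
        break;
      if (eps < 1e-10 || eps > 1e3) break;
    }
    eps = std::min(std::max(eps, 1e-8), 10.0);
  }

  // dual averaging (Nesterov) toward target acceptance
  double mu_da = std::log(10.0 * eps), logebar = std::log(eps), hbar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  int da_n = 0;

  // Welford accumulators for diagonal mass adaptation
  std::vector<double> wm(D, 0.0), ws(D, 0.0);
  long wn = 0;
  const int w1 = (int)(0.15 * warmup), w2 = (int)(0.5 * warmup),
            w3 = (int)(0.85 * warmup);

  const int n_post = iter - warmup;
  const int n_store = n_post / thin;
  NumericMatrix draws(n_store > 0 ? n_store : 0, D);
  int stored = 0, ndiv = 0;
  double acc_sum = 0.0;
  int acc_n = 0;

  for (int it = 0; it < iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    double ke0 = 0.0;
    for (int d = 0; d < D; ++d) {
      mom[d] = norm_rand() / std::sqrt(minv[d]);
      ke0 += 0.5 * minv[d] * mom[d] * mom[d];
    }
    const double H0 = -lp + ke0;
    std::copy(th.begin(), th.end(), thp.begin());
    std::copy(g.begin(), g.end(), gp.begin());
    int L = 1 + (int)(unif_rand() * max_leapfrog);
    if (L > max_leapfrog) L = max_leapfrog;

    double lpp = lp;
    bool bad = false;
    for (int s = 0; s < L; ++s) {
      for (int d = 0; d < D; ++d) mom[d] += 0.5 * eps * gp[d];
      for (int d = 0; d < D; ++d) thp[d] += eps * minv[d] * mom[d];
      lpp = m.logpost_grad(thp.data(), gp.data());
      if (!std::isfinite(lpp)) { bad = true; break; }
      for (int d = 0; d < D; ++d) mom[d] += 0.5 * eps * gp[d];
    }
    double a_prob = 0.0;
    bool diverged = bad;
    if (!bad) {
      double ke1 = 0.0;
      for (int d = 0; d < D; ++d) ke1 += 0.5 * minv[d] * mom[d] * mom[d];
      double dH = H0 - (-lpp + ke1);
      if (dH < -1000.0 || !std::isfinite(dH)) diverged = true;
      else a_prob = dH >= 0.0 ? 1.0 : std::exp(dH);
    }
    if (!diverged && unif_rand() < a_prob) {
      th.swap(thp); g.swap(gp); lp = lpp;
    }

    if (it < warmup) {
      ++da_n;
      hbar = (1.0 - 1.0 / (da_n + t0)) * hbar +
             (target_accept - a_prob) / (da_n + t0);
      double leps = mu_da - std::sqrt((double)da_n) / gamma_da * hbar;
      leps = std::min(std::max(leps, std::log(1e-10)), std::log(1e2));
      double pw = std::pow((double)da_n, -kappa);
      logebar = pw * leps + (1.0 - pw) * logebar;
      eps = std::exp(leps);

      if (it >= w1 && it < w3) {
        ++wn;
        for (int d = 0; d < D; ++d) {
          double dd = th[d] - wm[d];
          wm[d] += dd / wn;
          ws[d] += dd * (th[d] - wm[d]);
        }
      }
      if ((it + 1 == w2 || it + 1 == w3) && wn >= 10) {
        for (int d = 0; d < D; ++d) {
          double v = ws[d] / (wn - 1);
          minv[d] = (wn / (wn + 5.0)) * v + 1e-3 * (5.0 / (wn + 5.0));
          if (minv[d] < 1e-10) minv[d] = 1e-10;
        }
        std::fill(wm.begin(), wm.end(), 0.0);
        std::fill(ws.begin(), ws.end(), 0.0);
        wn = 0;
        eps = std::exp(logebar);
        mu_da = std::log(10.0 * eps);
        hbar = 0.0; da_n = 0; logebar = std::log(eps);
      }
      if (it == warmup - 1) eps = std::exp(logebar);
    } else {
      acc_sum += a_prob; ++acc_n;
      if (diverged) ++ndiv;
      int post = it - warmup;
      if ((post + 1) % thin == 0 && stored < n_store) {
        for (int d = 0; d < D; ++d) draws(stored, d) = th[d];
        ++stored;
      }
    }
  }

  return List::create(
      _["draws"] = draws,
      _["accept_rate"] = acc_n > 0 ? acc_sum / acc_n : NA_REAL,
      _["divergences"] = ndiv,
      _["step_size"] = eps,
      _["inv_mass"] = NumericVector(minv.begin(), minv.end()));
}
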