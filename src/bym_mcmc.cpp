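// Single-chain MCMC for the Besag-York-Mollie Poisson model:
//   O_i ~ Poisson(E_i * exp(eta_i)),
//   eta_i = alpha + x_i' beta + u_i + v_i,
//   u_i ~ N(0, sigma_u^2)  (unstructured),
//   v   ~ intrinsic CAR over the contiguity graph with conditional variance
//         sigma_v^2 / m_i, identified by post-sweep sum-to-zero centring,
//   alpha, beta_k ~ N(0, beta_sd^2),  sigma_u, sigma_v ~ Uniform(0, upper).
//
// Sampler: single-site adaptive random-walk Metropolis on alpha, each
// beta_k, each u_i and each v_i (proposal scales adapted toward 0.44
// acceptance during burn-in only, preserving detailed balance afterwards);
// shrinkage slice sampling on the two standard deviations.

#include <Rcpp.h>
#include <cmath>
#include <numeric>
using namespace Rcpp;

// log f(s) = -k log(s) - ss / (2 s^2) on (0, upper); shrinkage slice sampler
static double slice_sd(double cur, double k, double ss, double upper) {
  auto logf = [&](double s) { return -k * std::log(s) - ss / (2.0 * s * s); };
  double y = logf(cur) - R::exp_rand();
  double lo = upper * 1e-12, hi = upper;
  for (int it = 0; it < 200; ++it) {
    double prop = R::runif(lo, hi);
    if (logf(prop) >= y) return prop;
    if (prop < cur) lo = prop; else hi = prop;
  }
  return cur;
}

// [[Rcpp::export]]
List bym_chain_cpp(IntegerVector O, NumericVector E, NumericMatrix X,
                   List nb, IntegerMatrix edges, double icar_rank,
                   int n_iter, int n_burnin, int thin,
                   double sd_upper_u, double sd_upper_v, double beta_sd,
                   double alpha0, NumericVector beta0,
                   NumericVector u0, NumericVector v0,
                   double su0, double sv0) {
  const int N = O.size(), K = X.ncol();
  const int n_edges = edges.nrow();
  const int n_store = (n_iter - n_burnin) / thin;
  if (n_store < 1) stop("n_iter must exceed n_burnin by at least `thin`");

  // flatten neighbour lists (0-based)
  std::vector<std::vector<int>> adj(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = nb[i];
    for (int j = 0; j < v.size(); ++j) adj[i].push_back(v[j] - 1);
  }
  std::vector<int> m(N);
  int n_free = 0;
  for (int i = 0; i < N; ++i) { m[i] = (int)adj[i].size(); if (m[i] > 0) ++n_free; }

  double alpha = alpha0, sigma_u = su0, sigma_v = sv0;
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> eta(N), mu(N);
  double sumO = 0;
  for (int i = 0; i < N; ++i) sumO += O[i];
  auto refresh = [&]() {
    for (int i = 0; i < N; ++i) {
      double xb = 0;
      for (int k = 0; k < K; ++k) xb += X(i, k) * beta[k];
      eta[i] = alpha + xb + u[i] + v[i];
      mu[i] = E[i] * std::exp(eta[i]);
      if (!std::isfinite(mu[i]))
        stop("non-finite Poisson mean at area %d (eta = %g)", i + 1, eta[i]);
    }
  };
  refresh();

  // adaptive proposal log-scales and acceptance counters
  double ls_alpha = std::log(0.1);
  std::vector<double> ls_beta(K, std::log(0.1)), ls_u(N, std::log(0.5)),
      ls_v(N, std::log(0.5));
  double ls_scale_u = std::log(0.1), ls_scale_v = std::log(0.1);
  double acc_scale_u = 0, acc_scale_v = 0;
  double win_acc_scale_u = 0, win_acc_scale_v = 0;
  long tot_scale = 0;
  long win_scale_u = 0, win_scale_v = 0;
  double acc_alpha = 0;
  std::vector<double> acc_beta(K, 0), acc_u(N, 0), acc_v(N, 0);
  long tot_alpha = 0, tot_beta = 0, tot_u = 0, tot_v = 0;
  long win_alpha = 0;
  std::vector<long> win_beta(K, 0), win_u(N, 0), win_v(N, 0);
  double win_acc_alpha = 0;
  std::vector<double> win_acc_beta(K, 0), win_acc_u(N, 0), win_acc_v(N, 0);

  NumericVector s_alpha(n_store), s_su(n_store), s_sv(n_store), s_dev(n_store);
  NumericMatrix s_beta(n_store, K), s_u(n_store, N), s_v(n_store, N),
      s_eta(n_store, N);

  RNGScope scope;
  int stored = 0, batch = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- alpha: shift of all eta by d
    {
      double d = std::exp(ls_alpha) * R::norm_rand();
      double sumMu = 0;
      for (int i = 0; i < N; ++i) sumMu += mu[i];
      double a1 = alpha + d;
      double dll = d * sumO - (std::exp(d) - 1.0) * sumMu +
                   (alpha * alpha - a1 * a1) / (2.0 * beta_sd * beta_sd);
      if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
        alpha = a1;
        double ed = std::exp(d);
        for (int i = 0; i < N; ++i) { eta[i] += d; mu[i] *= ed; }
        acc_alpha += 1; win_acc_alpha += 1;
      }
      ++tot_alpha; ++win_alpha;
    }
    // ---- beta_k
    for (int k = 0; k < K; ++k) {
      double d = std::exp(ls_beta[k]) * R::norm_rand();
      double b1 = beta[k] + d;
      double dll = (beta[k] * beta[k] - b1 * b1) / (2.0 * beta_sd * beta_sd);
      for (int i = 0; i < N; ++i) {
        double de = X(i, k) * d;
        dll += O[i] * de - mu[i] * (std::exp(de) - 1.0);
      }
      if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
        beta[k] = b1;
        for (int i = 0; i < N; ++i) {
          double de = X(i, k) * d;
          eta[i] += de; mu[i] *= std::exp(de);
        }
        acc_beta[k] += 1; win_acc_beta[k] += 1;
      }
      ++tot_beta; ++win_beta[k];
    }
    // ---- u_i
    {
      double inv2s2 = 1.0 / (2.0 * sigma_u * sigma_u);
      for (int i = 0; i < N; ++i) {
        double d = std::exp(ls_u[i]) * R::norm_rand();
        double u1 = u[i] + d;
        double dll = O[i] * d - mu[i] * (std::exp(d) - 1.0) +
                     (u[i] * u[i] - u1 * u1) * inv2s2;
        if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
          u[i] = u1; eta[i] += d; mu[i] *= std::exp(d);
          acc_u[i] += 1; win_acc_u[i] += 1;
        }
        ++tot_u; ++win_u[i];
      }
    }
    // ---- v_i (islands stay fixed at 0)
    {
      double inv2s2 = 1.0 / (2.0 * sigma_v * sigma_v);
      for (int i = 0; i < N; ++i) {
        if (m[i] == 0) continue;
        double vbar = 0;
        for (int j : adj[i]) vbar += v[j];
        vbar /= m[i];
        double d = std::exp(ls_v[i]) * R::norm_rand();
        double v1 = v[i] + d;
        double dll = O[i] * d - mu[i] * (std::exp(d) - 1.0) +
                     m[i] * inv2s2 *
                         ((v[i] - vbar) * (v[i] - vbar) - (v1 - vbar) * (v1 - vbar));
        if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
          v[i] = v1; eta[i] += d; mu[i] *= std::exp(d);
          acc_v[i] += 1; win_acc_v[i] += 1;
        }
        ++tot_v; ++win_v[i];
      }
    }
    // ---- recentre v (sum-to-zero over non-islands), absorb into alpha
    {
      double mbar = 0;
      for (int i = 0; i < N; ++i) if (m[i] > 0) mbar += v[i];
      mbar /= n_free;
      for (int i = 0; i < N; ++i) {
        if (m[i] > 0) v[i] -= mbar;
        else { eta[i] += mbar; mu[i] *= std::exp(mbar); }  // islands: v fixed 0
      }
      alpha += mbar;
    }
    // ---- joint scale moves: (u, sigma_u) -> (c u, c sigma_u), likewise v.
    // The Gaussian prior terms cancel, leaving log c from the Jacobian, so
    // the whole field can rescale in one step; this decorrelates the SDs
    // from their fields, which single-site updates mix slowly.
    {
      double d = std::exp(ls_scale_u) * R::norm_rand();
      double c = std::exp(d);
      if (sigma_u * c < sd_upper_u) {
        double dll = d;  // prior x Jacobian
        for (int i = 0; i < N; ++i) {
          double de = (c - 1.0) * u[i];
          dll += O[i] * de - mu[i] * (std::exp(de) - 1.0);
        }
        if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
          for (int i = 0; i < N; ++i) {
            double de = (c - 1.0) * u[i];
            u[i] *= c; eta[i] += de; mu[i] *= std::exp(de);
          }
          sigma_u *= c;
          acc_scale_u += 1; win_acc_scale_u += 1;
        }
      }
      ++tot_scale; ++win_scale_u;
    }
    if (n_free > 0) {
      double d = std::exp(ls_scale_v) * R::norm_rand();
      double c = std::exp(d);
      if (sigma_v * c < sd_upper_v) {
        double dll = d;
        for (int i = 0; i < N; ++i) {
          if (m[i] == 0) continue;
          double de = (c - 1.0) * v[i];
          dll += O[i] * de - mu[i] * (std::exp(de) - 1.0);
        }
        if (std::isfinite(dll) && std::log(R::unif_rand()) < dll) {
          for (int i = 0; i < N; ++i) {
            if (m[i] == 0) continue;
            double de = (c - 1.0) * v[i];
            v[i] *= c; eta[i] += de; mu[i] *= std::exp(de);
          }
          sigma_v *= c;
          acc_scale_v += 1; win_acc_scale_v += 1;
        }
      }
      ++win_scale_v;
    }
    // ---- sigma_u, sigma_v by slice sampling
    {
      double ssu = 0;
      for (int i = 0; i < N; ++i) ssu += u[i] * u[i];
      sigma_u = slice_sd(sigma_u, (double)N, ssu, sd_upper_u);
      double ssv = 0;
      for (int e = 0; e < n_edges; ++e) {
        double dv = v[edges(e, 0) - 1] - v[edges(e, 1) - 1];
        ssv += dv * dv;
      }
      sigma_v = slice_sd(sigma_v, icar_rank, ssv, sd_upper_v);
    }
    // ---- adapt proposal scales during burn-in
    if (iter < n_burnin && (iter + 1) % 50 == 0) {
      ++batch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
      auto tune = [&](double& ls, double& acc, long& n) {
        if (n > 0) ls += (acc / n > 0.44 ? delta : -delta);
        acc = 0; n = 0;
      };
      tune(ls_alpha, win_acc_alpha, win_alpha);
      tune(ls_scale_u, win_acc_scale_u, win_scale_u);
      tune(ls_scale_v, win_acc_scale_v, win_scale_v);
      for (int k = 0; k < K; ++k) tune(ls_beta[k], win_acc_beta[k], win_beta[k]);
      for (int i = 0; i < N; ++i) { tune(ls_u[i], win_acc_u[i], win_u[i]);
                                    tune(ls_v[i], win_acc_v[i], win_v[i]); }
    }
    // ---- store
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0 && stored < n_store) {
      s_alpha[stored] = alpha; s_su[stored] = sigma_u; s_sv[stored] = sigma_v;
      for (int k = 0; k < K; ++k) s_beta(stored, k) = beta[k];
      double dev = 0;
      for (int i = 0; i < N; ++i) {
        s_u(stored, i) = u[i]; s_v(stored, i) = v[i]; s_eta(stored, i) = eta[i];
        dev += (O[i] > 0 ? O[i] * std::log(mu[i]) : 0.0) - mu[i] -
               R::lgammafn(O[i] + 1.0);
      }
      s_dev[stored] = -2.0 * dev;
      ++stored;
    }
    if ((iter + 1) % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rates = NumericVector::create(
      _["alpha"] = acc_alpha / tot_alpha,
      _["beta"] = (K > 0 ? std::accumulate(acc_beta.begin(), acc_beta.end(), 0.0) /
                               tot_beta : NA_REAL),
      _["u"] = std::accumulate(acc_u.begin(), acc_u.end(), 0.0) / tot_u,
      _["v"] = (tot_v > 0 ? std::accumulate(acc_v.begin(), acc_v.end(), 0.0) /
                                tot_v : NA_REAL),
      _["scale_u"] = acc_scale_u / tot_scale,
      _["scale_v"] = (n_free > 0 ? acc_scale_v / tot_scale : NA_REAL));
  return List::create(_["alpha"] = s_alpha, _["beta"] = s_beta,
                      _["sigma_u"] = s_su, _["sigma_v"] = s_sv,
                      _["u"] = s_u, _["v"] = s_v, _["eta"] = s_eta,
                      _["deviance"] = s_dev, _["acceptance"] = acc_rates);
}
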