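// Likelihood kernel and adaptive Metropolis-within-Gibbs sampler for the
// hierarchical EWA learning models. The observed-data likelihood factorises
// over individuals (window tallies are functions of the data only), so
// individual offset blocks, cell-mean scalars and offset scales can be
// updated with exact conditional acceptance ratios.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parameter codes: 0 lambda (log), 1 phi (logit), 2 gamma (logit),
//                  3 f (log), 4 beta (identity)
static inline double linkinv(int par, double x) {
  if (x > 30.0) x = 30.0;
  if (x < -30.0) x = -30.0;
  switch (par) {
  case 0: case 3: return std::exp(x);
  case 1: case 2: return 1.0 / (1.0 + std::exp(-x));
  default: return x;
  }
}


static inline double accept_prob(double dlp) {
  if (std::isnan(dlp)) return 0.0;
  return dlp >= 0.0 ? 1.0 : std::exp(dlp);
}

struct EwaData {
  int n_ind, n_ev, strategy;  // strategy: 0 ind, 1 freq, 2 male, 3 adult, 4 roost
  IntegerVector ptr;          // n_ind + 1, 0-based event offsets per individual
  IntegerVector choice;       // 1-based option index per event
  NumericVector payoff;
  NumericMatrix N, male, adult, same;  // n_ev x 2 window counts
  NumericMatrix A0;                    // n_ind x 2 initial attractions
};

static EwaData unpack(const List& data) {
  EwaData d;
  d.ptr = data["ptr"];
  d.choice = data["choice"];
  d.payoff = data["payoff"];
  d.N = as<NumericMatrix>(data["N"]);
  d.male = as<NumericMatrix>(data["male"]);
  d.adult = as<NumericMatrix>(data["adult"]);
  d.same = as<NumericMatrix>(data["same"]);
  d.A0 = as<NumericMatrix>(data["A0"]);
  d.strategy = as<int>(data["strategy"]);
  d.n_ind = d.ptr.size() - 1;
  d.n_ev = d.choice.size();
  return d;
}

// log-likelihood of individual i at natural-scale parameters
// th = {lambda, phi, gamma, f, beta}; pw (optional) receives pointwise terms
static double loglik_ind(const EwaData& d, int i, const double* th,
                         double* pw = nullptr) {
  const double lambda = th[0], phi = th[1], gamma = th[2], f = th[3],
    beta = th[4];
  double a0 = d.A0(i, 0), a1 = d.A0(i, 1);
  double ll = 0.0;
  for (int e = d.ptr[i]; e < d.ptr[i + 1]; ++e) {
    double z0 = lambda * a0, z1 = lambda * a1;
    double m = z0 > z1 ? z0 : z1;
    double e0 = std::exp(z0 - m), e1 = std::exp(z1 - m);
    double I0 = e0 / (e0 + e1);
    double P0 = I0, P1 = 1.0 - I0;
    if (d.strategy != 0) {
      double S0 = 0.0;
      bool have = false;
      if (d.strategy == 1) {
        double n0 = d.N(e, 0), n1 = d.N(e, 1);
        if (n0 + n1 > 0.0) {
          // log-scale form of n0^f / (n0^f + n1^f); robust to large f
          if (n0 == 0.0) S0 = 0.0;
          else if (n1 == 0.0) S0 = 1.0;
          else {
            double t = f * (std::log(n1) - std::log(n0));
            S0 = (t > 700.0) ? 0.0 : 1.0 / (1.0 + std::exp(t));
          }
          have = true;
        }
      } else if (d.strategy == 2 || d.strategy == 3) {
        const NumericMatrix& cat = (d.strategy == 2) ? d.male : d.adult;
        double n0 = cat(e, 0), n1 = cat(e, 1);
        if (n0 + n1 > 0.0) {
          S0 = n0 / (n0 + n1);
          have = true;
        }
      } else {  // roost cue bias: same-roost demos weighted exp(beta)
        double n0 = d.N(e, 0), n1 = d.N(e, 1);
        if (n0 + n1 > 0.0) {
          double eb = std::exp(beta > 30.0 ? 30.0 : beta);
          double w0 = d.same(e, 0) * eb + (n0 - d.same(e, 0));
          double w1 = d.same(e, 1) * eb + (n1 - d.same(e, 1));
          S0 = w0 / (w0 + w1);
          have = true;
        }
      }
      if (have) {
        P0 = (1.0 - gamma) * I0 + gamma * S0;
        P1 = 1.0 - P0;
      }
    }
    double p = (d.choice[e] == 1) ? P0 : P1;
    if (p < 1e-12) p = 1e-12;
    double lp = std::log(p);
    ll += lp;
    if (pw) pw[e] = lp;
    if (d.choice[e] == 1)
      a0 = (1.0 - phi) * a0 + phi * d.payoff[e];
    else
      a1 = (1.0 - phi) * a1 + phi * d.payoff[e];
  }
  return ll;
}

// [[Rcpp::export]]
List ewa_loglik_grouped(List data, NumericMatrix theta_nat) {
  EwaData d = unpack(data);
  if (theta_nat.nrow() != d.n_ind || theta_nat.ncol() != 5)
    stop("theta_nat must be n_ind x 5 (lambda, phi, gamma, f, beta)");
  NumericVector pw(d.n_ev);
  double total = 0.0;
  std::vector<double> th(5);
  for (int i = 0; i < d.n_ind; ++i) {
    for (int p = 0; p < 5; ++p) th[p] = theta_nat(i, p);
    total += loglik_ind(d, i, th.data(), &pw[0]);
  }
  return List::create(_["loglik"] = total, _["pointwise"] = pw);
}

// [[Rcpp::export]]
List ewa_mcmc(List data, IntegerVector cell, int n_cell, IntegerVector active,
              int warmup, int n_save, bool prior_only, double init_sd,
              int thin = 1, double mu_prior_sd = 1.0,
              double sigma_prior_rate = 1.0) {
  RNGScope scope;
  EwaData d = unpack(data);
  const int P = active.size();
  const int n_ind = d.n_ind;
  if (cell.size() != n_ind) stop("cell index length mismatch");

  std::vector<std::vector<double>> mu(P, std::vector<double>(n_cell));
  std::vector<double> sigma(P, 0.5);
  std::vector<std::vector<double>> off(P, std::vector<double>(n_ind, 0.0));
  for (int p = 0; p < P; ++p)
    for (int c = 0; c < n_cell; ++c) mu[p][c] = R::rnorm(0.0, init_sd);

  // natural-scale parameter vector for individual i
  auto theta_i = [&](int i, double* th) {
    th[0] = linkinv(0, 0.0);  // placeholders; overwritten for active codes
    th[1] = 0.5; th[2] = 0.0; th[3] = 1.0; th[4] = 0.0;
    for (int p = 0; p < P; ++p) {
      int code = active[p];
      th[code] = linkinv(code, mu[p][cell[i]] + off[p][i]);
    }
  };
  auto ll_of = [&](int i) {
    if (prior_only) return 0.0;
    double th[5];
    theta_i(i, th);
    return loglik_ind(d, i, th);
  };

  std::vector<double> ll_ind(n_ind);
  for (int i = 0; i < n_ind; ++i) ll_ind[i] = ll_of(i);

  std::vector<double> s_ind(n_ind, 0.2);
  std::vector<std::vector<double>> s_mu(P, std::vector<double>(n_cell, 0.2));
  std::vector<double> s_sig(P, 0.3);
  std::vector<double> s_nc(P, 0.3);

  // individuals grouped by cell for the mean updates
  std::vector<std::vector<int>> cell_members(n_cell);
  for (int i = 0; i < n_ind; ++i) cell_members[cell[i]].push_back(i);

  if (thin < 1) thin = 1;
  const int n_iter = (warmup + n_save) * thin;
  const int warm_iter = warmup * thin;
  const int n_store = P * n_cell + P + P * n_ind;
  NumericMatrix draws(n_save, n_store);
  NumericMatrix pointwise(prior_only ? 1 : n_save, prior_only ? 1 : d.n_ev);
  NumericVector lp_save(n_save);

  std::vector<double> prop(P);
  for (int t = 1; t <= n_iter; ++t) {
    const bool adapting = t <= warm_iter;
    const double rate = std::pow((double)t, -0.6);

    // 1. individual offset blocks
    for (int i = 0; i < n_ind; ++i) {
      double lp0 = ll_ind[i];
      double lp1;
      for (int p = 0; p < P; ++p) {
        prop[p] = off[p][i] + s_ind[i] * R::norm_rand();
        lp0 += R::dnorm(off[p][i], 0.0, sigma[p], 1);
      }
      std::vector<double> old(P);
      for (int p = 0; p < P; ++p) { old[p] = off[p][i]; off[p][i] = prop[p]; }
      lp1 = ll_of(i);
      double lq1 = lp1;
      for (int p = 0; p < P; ++p) lq1 += R::dnorm(off[p][i], 0.0, sigma[p], 1);
      double alpha = accept_prob(lq1 - lp0);
      if (R::unif_rand() < alpha) {
        ll_ind[i] = lp1;
      } else {
        for (int p = 0; p < P; ++p) off[p][i] = old[p];
      }
      if (adapting) s_ind[i] *= std::exp(rate * (alpha - 0.3));
    }

    // 2. cell means, one scalar at a time
    for (int p = 0; p < P; ++p) {
      for (int c = 0; c < n_cell; ++c) {
        double old_mu = mu[p][c];
        double new_mu = old_mu + s_mu[p][c] * R::norm_rand();
        double dlp = R::dnorm(new_mu, 0.0, mu_prior_sd, 1) -
          R::dnorm(old_mu, 0.0, mu_prior_sd, 1);
        std::vector<double> new_ll(cell_members[c].size());
        mu[p][c] = new_mu;
        for (size_t k = 0; k < cell_members[c].size(); ++k) {
          int i = cell_members[c][k];
          new_ll[k] = ll_of(i);
          dlp += new_ll[k] - ll_ind[i];
        }
        double alpha = accept_prob(dlp);
        if (R::unif_rand() < alpha) {
          for (size_t k = 0; k < cell_members[c].size(); ++k)
            ll_ind[cell_members[c][k]] = new_ll[k];
        } else {
          mu[p][c] = old_mu;
        }
        if (adapting) s_mu[p][c] *= std::exp(rate * (alpha - 0.44));
      }
    }

    // 3. offset scales, random walk on log sigma (Exponential(1) prior)
    for (int p = 0; p < P; ++p) {
      double ls_old = std::log(sigma[p]);
      double ls_new = ls_old + s_sig[p] * R::norm_rand();
      double s_new = std::exp(ls_new);
      double dlp = sigma_prior_rate * (sigma[p] - s_new) + (ls_new - ls_old);  // prior + jacobian
      for (int i = 0; i < n_ind; ++i)
        dlp += R::dnorm(off[p][i], 0.0, s_new, 1) -
          R::dnorm(off[p][i], 0.0, sigma[p], 1);
      double alpha = accept_prob(dlp);
      if (R::unif_rand() < alpha) sigma[p] = s_new;
      if (adapting) s_sig[p] *= std::exp(rate * (alpha - 0.44));
    }

    // 4. non-centered rescaling: move sigma while holding off/sigma fixed
    // (escapes the funnel when the offset scale is small). In non-centered
    // coordinates the offset prior cancels; the ratio needs the data
    // likelihood, the Exponential(1) prior and one jacobian term.
    for (int p = 0; p < P; ++p) {
      double ls_old = std::log(sigma[p]);
      double ls_new = ls_old + s_nc[p] * R::norm_rand();
      double s_new = std::exp(ls_new);
      double scale = s_new / sigma[p];
      std::vector<double> old_off(n_ind), new_ll(n_ind);
      double dlp = sigma_prior_rate * (sigma[p] - s_new) + (ls_new - ls_old);
      double sigma_old = sigma[p];
      for (int i = 0; i < n_ind; ++i) old_off[i] = off[p][i];
      for (int i = 0; i < n_ind; ++i) off[p][i] *= scale;
      sigma[p] = s_new;
      for (int i = 0; i < n_ind; ++i) {
        new_ll[i] = ll_of(i);
        dlp += new_ll[i] - ll_ind[i];
      }
      double alpha = accept_prob(dlp);
      if (R::unif_rand() < alpha) {
        for (int i = 0; i < n_ind; ++i) ll_ind[i] = new_ll[i];
      } else {
        sigma[p] = sigma_old;
        for (int i = 0; i < n_ind; ++i) off[p][i] = old_off[i];
      }
      if (adapting) s_nc[p] *= std::exp(rate * (alpha - 0.44));
    }

    if (t > warm_iter && (t - warm_iter) % thin == 0) {
      int r = (t - warm_iter) / thin - 1;
      int col = 0;
      for (int p = 0; p < P; ++p)
        for (int c = 0; c < n_cell; ++c) draws(r, col++) = mu[p][c];
      for (int p = 0; p < P; ++p) draws(r, col++) = sigma[p];
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < n_ind; ++i) draws(r, col++) = off[p][i];
      double lp = 0.0;
      if (!prior_only) {
        double th[5];
        std::vector<double> pwbuf(d.n_ev);
        for (int i = 0; i < n_ind; ++i) {
          theta_i(i, th);
          lp += loglik_ind(d, i, th, pwbuf.data());
        }
        for (int e = 0; e < d.n_ev; ++e) pointwise(r, e) = pwbuf[e];
      }
      lp_save[r] = lp;
    }
  }

  return List::create(_["draws"] = draws, _["pointwise"] = pointwise,
                      _["lp"] = lp_save);
}
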