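// Q-learning likelihood replay and an adaptive Metropolis-within-Gibbs
// sampler for the hierarchical models. Parameters live on an unconstrained
// scale (probit link for learning rates, log link for the inverse
// temperature) with a non-centered subject-level parameterization.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct TaskData {
  // flattened per-trial arrays, subjects contiguous
  std::vector<int> pair_id;   // 0-based stimulus pair
  std::vector<int> choice;    // 0/1, -1 = no response
  std::vector<int> ttype;     // 0 gain, 1 loss, 2 neutral
  std::vector<double> outcome;
  std::vector<int> offset;    // length n_subj + 1
  int n_pairs;
  int n_subj;
};

// log-likelihood of one subject's choices under (aG, aL, beta); optionally
// writes per-trial log-likelihoods into ll_out at the global trial index.
double subj_loglik(const TaskData& d, int s, double aG, double aL,
                   double beta, double* ll_out = nullptr) {
  std::vector<double> Q(d.n_pairs * 2, 0.0);
  double ll = 0.0;
  for (int t = d.offset[s]; t < d.offset[s + 1]; ++t) {
    int ch = d.choice[t];
    if (ch < 0) {            // no-response: contributes 0, no update
      if (ll_out) ll_out[t] = 0.0;
      continue;
    }
    int p = d.pair_id[t];
    double q0 = beta * Q[2 * p], q1 = beta * Q[2 * p + 1];
    double m = q0 > q1 ? q0 : q1;
    double lse = m + std::log(std::exp(q0 - m) + std::exp(q1 - m));
    double lt = (ch == 0 ? q0 : q1) - lse;
    ll += lt;
    if (ll_out) ll_out[t] = lt;
    double alpha = (d.ttype[t] == 1) ? aL : aG;
    double& qc = Q[2 * p + ch];
    qc += alpha * (d.outcome[t] - qc);
  }
  return ll;
}

inline double probit(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }
inline double beta_link(double b) { return std::exp(b > 7.0 ? 7.0 : b); }

TaskData build_data(const IntegerVector& subj, const IntegerVector& pair_id,
                    const IntegerVector& choice, const IntegerVector& ttype,
                    const NumericVector& outcome, int n_subj) {
  TaskData d;
  int n = subj.size();
  d.pair_id.assign(pair_id.begin(), pair_id.end());
  d.choice.assign(choice.begin(), choice.end());
  d.ttype.assign(ttype.begin(), ttype.end());
  d.outcome.assign(outcome.begin(), outcome.end());
  d.n_subj = n_subj;
  d.offset.assign(n_subj + 1, 0);
  for (int i = 0; i < n; ++i) {
    if (subj[i] < 0 || subj[i] >= n_subj) stop("subject index out of range");
    d.offset[subj[i] + 1]++;
  }
  for (int s = 0; s < n_subj; ++s) {
    d.offset[s + 1] += d.offset[s];
    // require contiguous, sorted subjects
  }
  for (int i = 1; i < n; ++i) {
    if (subj[i] < subj[i - 1]) stop("trials must be sorted by subject");
  }
  d.n_pairs = 0;
  for (int i = 0; i < n; ++i) {
    if (d.pair_id[i] + 1 > d.n_pairs) d.n_pairs = d.pair_id[i] + 1;
  }
  return d;
}

} // namespace

// [[Rcpp::export]]
NumericVector pointwise_ll_cpp(IntegerVector subj, IntegerVector pair_id,
                               IntegerVector choice, IntegerVector ttype,
                               NumericVector outcome, int n_subj,
                               NumericVector alpha_gain,
                               NumericVector alpha_loss,
                               NumericVector beta) {
  TaskData d = build_data(subj, pair_id, choice, ttype, outcome, n_subj);
  NumericVector out(subj.size());
  for (int s = 0; s < n_subj; ++s) {
    subj_loglik(d, s, alpha_gain[s], alpha_loss[s], beta[s],
                REAL(out));
  }
  return out;
}

// [[Rcpp::export]]
List mcmc_qlearn_cpp(IntegerVector subj, IntegerVector pair_id,
                     IntegerVector choice, IntegerVector ttype,
                     NumericVector outcome, int n_subj,
                     IntegerVector group,  // 0-based group per subject
                     int n_group, int model_id,
                     int n_chains, int n_warmup, int n_iter,
                     int seed, double prior_loc_sd, double prior_scale_sd) {
  TaskData d = build_data(subj, pair_id, choice, ttype, outcome, n_subj);
  const int P = (model_id == 1) ? 2 : 3;   // (aG[,aL],b) unconstrained
  const int n_trials = subj.size();
  const int n_keep = n_chains * n_iter;

  NumericMatrix group_draws(n_keep, n_group * P * 2);
  NumericMatrix subject_draws(n_keep, n_subj * 3); // natural aG, aL, beta
  NumericMatrix log_lik(n_keep, n_trials);
  IntegerVector chain_id(n_keep);
  NumericVector accept_subj(n_chains), accept_group(n_chains);

  // natural-scale params of subject s given state
  auto naturals = [&](const std::vector<double>& mu,
                      const std::vector<double>& sg,
                      const std::vector<double>& z,
                      int s, double& aG, double& aL, double& beta) {
    int g = group[s];
    double uG = mu[g * P + 0] + sg[g * P + 0] * z[s * P + 0];
    aG = probit(uG);
    if (P == 3) {
      double uL = mu[g * P + 1] + sg[g * P + 1] * z[s * P + 1];
      aL = probit(uL);
      beta = beta_link(mu[g * P + 2] + sg[g * P + 2] * z[s * P + 2]);
    } else {
      aL = aG;
      beta = beta_link(mu[g * P + 1] + sg[g * P + 1] * z[s * P + 1]);
    }
  };

  for (int c = 0; c < n_chains; ++c) {
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 1000003u + c + 1);
    std::normal_distribution<double> rnormal(0.0, 1.0);
    std::uniform_real_distribution<double> runif(0.0, 1.0);

    std::vector<double> mu(n_group * P), lsg(n_group * P), sg(n_group * P);
    std::vector<double> z(n_subj * P);
    for (auto& v : mu) v = 0.3 * rnormal(rng);
    for (auto& v : lsg) v = std::log(0.5) + 0.2 * rnormal(rng);
    for (size_t i = 0; i < sg.size(); ++i) sg[i] = std::exp(lsg[i]);
    for (auto& v : z) v = 0.5 * rnormal(rng);

    std::vector<double> cur_ll(n_subj);
    auto refresh_ll = [&](int s) {
      double aG, aL, beta;
      naturals(mu, sg, z, s, aG, aL, beta);
      cur_ll[s] = subj_loglik(d, s, aG, aL, beta);
    };
    for (int s = 0; s < n_subj; ++s) refresh_ll(s);

    // adaptive proposal scales
    std::vector<double> ps_z(n_subj * P, 0.5);
    std::vector<double> ps_mu(n_group * P, 0.2), ps_ls(n_group * P, 0.2);
    std::vector<int> acc_z(n_subj * P, 0), try_z(n_subj * P, 0);
    std::vector<int> acc_mu(n_group * P, 0), try_mu(n_group * P, 0);
    std::vector<int> acc_ls(n_group * P, 0), try_ls(n_group * P, 0);
    long long tot_acc_s = 0, tot_try_s = 0, tot_acc_g = 0, tot_try_g = 0;

    auto adapt = [](double& scale, int& acc, int& tries) {
      if (tries < 20) return;
      double rate = static_cast<double>(acc) / tries;
      if (rate > 0.5) scale *= 1.2;
      else if (rate < 0.3) scale *= 0.8;
      if (scale < 1e-3) scale = 1e-3;
      if (scale > 5.0) scale = 5.0;
      acc = 0; tries = 0;
    };

    int total_iter = n_warmup + n_iter;
    for (int it = 0; it < total_iter; ++it) {
      bool warm = it < n_warmup;

      // subject-level z updates (componentwise random walk)
      for (int s = 0; s < n_subj; ++s) {
        for (int p = 0; p < P; ++p) {
          int idx = s * P + p;
          double old = z[idx];
          double prop = old + ps_z[idx] * rnormal(rng);
          z[idx] = prop;
          double aG, aL, beta;
          naturals(mu, sg, z, s, aG, aL, beta);
          double new_ll = subj_loglik(d, s, aG, aL, beta);
          double la = new_ll - cur_ll[s] + 0.5 * (old * old - prop * prop);
          try_z[idx]++; tot_try_s++;
          if (std::log(runif(rng)) < la) {
            cur_ll[s] = new_ll; acc_z[idx]++; tot_acc_s++;
          } else {
            z[idx] = old;
          }
          if (warm) adapt(ps_z[idx], acc_z[idx], try_z[idx]);
        }
      }

      // group-level updates; changing (mu, sigma) moves every subject in
      // the group, so their likelihoods are re-evaluated jointly
      std::vector<double> new_ll(n_subj);
      for (int g = 0; g < n_group; ++g) {
        for (int p = 0; p < P; ++p) {
          int idx = g * P + p;
          // location
          {
            double old = mu[idx];
            double prop = old + ps_mu[idx] * rnormal(rng);
            mu[idx] = prop;
            double la = 0.5 * (old * old - prop * prop) /
                        (prior_loc_sd * prior_loc_sd);
            for (int s = 0; s < n_subj; ++s) {
              if (group[s] != g) continue;
              double aG, aL, beta;
              naturals(mu, sg, z, s, aG, aL, beta);
              new_ll[s] = subj_loglik(d, s, aG, aL, beta);
              la += new_ll[s] - cur_ll[s];
            }
            try_mu[idx]++; tot_try_g++;
            if (std::log(runif(rng)) < la) {
              for (int s = 0; s < n_subj; ++s) {
                if (group[s] == g) cur_ll[s] = new_ll[s];
              }
              acc_mu[idx]++; tot_acc_g++;
            } else {
              mu[idx] = old;
            }
            if (warm) adapt(ps_mu[idx], acc_mu[idx], try_mu[idx]);
          }
          // log-scale
          {
            double old = lsg[idx];
            double prop = old + ps_ls[idx] * rnormal(rng);
            double sig_old = std::exp(old), sig_new = std::exp(prop);
            lsg[idx] = prop; sg[idx] = sig_new;
            // half-normal(prior_scale_sd) prior + log-scale Jacobian
            double la = (sig_old * sig_old - sig_new * sig_new) /
                            (2.0 * prior_scale_sd * prior_scale_sd) +
                        (prop - old);
            for (int s = 0; s < n_subj; ++s) {
              if (group[s] != g) continue;
              double aG, aL, beta;
              naturals(mu, sg, z, s, aG, aL, beta);
              new_ll[s] = subj_loglik(d, s, aG, aL, beta);
              la += new_ll[s] - cur_ll[s];
            }
            try_ls[idx]++; tot_try_g++;
            if (std::log(runif(rng)) < la) {
              for (int s = 0; s < n_subj; ++s) {
                if (group[s] == g) cur_ll[s] = new_ll[s];
              }
              acc_ls[idx]++; tot_acc_g++;
            } else {
              lsg[idx] = old; sg[idx] = sig_old;
            }
            if (warm) adapt(ps_ls[idx], acc_ls[idx], try_ls[idx]);
          }
        }
      }

      if (!warm) {
        int row = c * n_iter + (it - n_warmup);
        chain_id[row] = c + 1;
        for (int g = 0; g < n_group; ++g) {
          for (int p = 0; p < P; ++p) {
            group_draws(row, g * P + p) = mu[g * P + p];
            group_draws(row, n_group * P + g * P + p) = sg[g * P + p];
          }
        }
        std::vector<double> buf(n_trials, 0.0);
        for (int s = 0; s < n_subj; ++s) {
          double aG, aL, beta;
          naturals(mu, sg, z, s, aG, aL, beta);
          subject_draws(row, s * 3 + 0) = aG;
          subject_draws(row, s * 3 + 1) = aL;
          subject_draws(row, s * 3 + 2) = beta;
          subj_loglik(d, s, aG, aL, beta, buf.data());
          for (int t = d.offset[s]; t < d.offset[s + 1]; ++t) {
            log_lik(row, t) = buf[t];
          }
        }
      }
    }
    accept_subj[c] = tot_try_s ? static_cast<double>(tot_acc_s) / tot_try_s : 0;
    accept_group[c] = tot_try_g ? static_cast<double>(tot_acc_g) / tot_try_g : 0;
  }

  return List::create(
    _["group_draws"] = group_draws,
    _["subject_draws"] = subject_draws,
    _["log_lik"] = log_lik,
    _["chain"] = chain_id,
    _["accept_subject"] = accept_subj,
    _["accept_group"] = accept_group
  );
}
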