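// Hierarchical Bayesian sampler for the softmax Q-learning model.
//
// Per-animal phase-specific learning rates (logit scale) and inverse
// temperatures (log scale) are non-centred around group-level hypermeans
// with half-normal hyperscales; initial odor values are shared across the
// cohort and anchored to mean zero. Inference is adaptive
// Metropolis-within-Gibbs: a joint proposal per animal's local effects,
// scalar proposals for each hyperparameter (evaluating only that group's
// likelihood), and a joint proposal for the shared values. Proposal scales
// adapt toward standard acceptance targets during warmup only.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct CohortData {
  std::vector<int> choice, reward, phase;  // concatenated trials
  std::vector<int> off;                    // K+1 offsets into trials
  std::vector<int> grp;                    // group index per animal
  int K, G, n_odors;
  double rmag;
  bool carry;
};

// Replay animal k's trials; optionally store per-trial log-probabilities.
static double animal_ll(const CohortData& D, int k, const double a[2],
                        const double b[2], const std::vector<double>& v,
                        double* pw) {
  std::vector<double> Q(v);
  double ll = 0.0;
  const int t0 = D.off[k], t1 = D.off[k + 1];
  int prevph = (t0 < t1) ? D.phase[t0] : 0;
  for (int t = t0; t < t1; ++t) {
    const int ph = D.phase[t];
    if (!D.carry && ph != prevph) Q.assign(v.begin(), v.end());
    prevph = ph;
    const int c = D.choice[t];
    const double bb = b[ph];
    double mx = bb * Q[0];
    for (int o = 1; o < D.n_odors; ++o) mx = std::max(mx, bb * Q[o]);
    double se = 0.0;
    for (int o = 0; o < D.n_odors; ++o) se += std::exp(bb * Q[o] - mx);
    const double lp = bb * Q[c] - mx - std::log(se);
    ll += lp;
    if (pw) pw[t - t0] = lp;
    const double r = D.reward[t] ? D.rmag : 0.0;
    Q[c] += a[ph] * (r - Q[c]);
  }
  return ll;
}

struct Priors {
  double mua_loc, mua_sc, sa_sc, mub_loc, mub_sc, sb_sc, v_sc;
};

struct State {
  // hyper: g-major, model-phase minor
  std::vector<double> mu_a, ls_a, mu_b, ls_b;
  // local non-centred effects: k-major
  std::vector<double> za, zb;
  // free components of the shared initial values (last odor pinned, then
  // mean-centred)
  std::vector<double> u;
};

static void v_from_u(const State& st, int n_odors, std::vector<double>& v) {
  double s = 0.0;
  for (int i = 0; i < n_odors - 1; ++i) s += st.u[i];
  const double m = s / n_odors;
  for (int i = 0; i < n_odors - 1; ++i) v[i] = st.u[i] - m;
  v[n_odors - 1] = -m;
}

static void animal_params(const CohortData& D, const State& st, int Pa,
                          int Pb, int k, double a[2], double b[2]) {
  const int g = D.grp[k];
  for (int ph = 0; ph < 2; ++ph) {
    const int ja = (Pa == 2) ? ph : 0;
    const int jb = (Pb == 2) ? ph : 0;
    a[ph] = invlogit(st.mu_a[g * Pa + ja] +
                     std::exp(st.ls_a[g * Pa + ja]) * st.za[k * Pa + ja]);
    double xb = st.mu_b[g * Pb + jb] +
                std::exp(st.ls_b[g * Pb + jb]) * st.zb[k * Pb + jb];
    if (xb > 25.0) xb = 25.0;
    if (xb < -25.0) xb = -25.0;
    b[ph] = std::exp(xb);
  }
}

static double lp_mu(double x, double loc, double sc) {
  const double d = (x - loc) / sc;
  return -0.5 * d * d;
}

// half-normal prior on sigma = exp(ls), plus the log-Jacobian of the
// log transform
static double lp_lsigma(double ls, double sc) {
  const double s = std::exp(ls);
  const double d = s / sc;
  return -0.5 * d * d + ls;
}

// [[Rcpp::export]]
List rl_mcmc_chain(IntegerVector choice, IntegerVector reward,
                   IntegerVector phase, IntegerVector offsets,
                   IntegerVector group, int n_groups, int n_odors,
                   double reward_mag, bool carry_over, bool alpha_ps,
                   bool beta_ps, int warmup, int draws, int seed,
                   List prior) {
  CohortData D;
  D.choice.assign(choice.begin(), choice.end());
  D.reward.assign(reward.begin(), reward.end());
  D.phase.assign(phase.begin(), phase.end());
  D.off.assign(offsets.begin(), offsets.end());
  D.grp.assign(group.begin(), group.end());
  D.K = (int)group.size();
  D.G = n_groups;
  D.n_odors = n_odors;
  D.rmag = reward_mag;
  D.carry = carry_over;
  const int Ttot = (int)choice.size();
  const int Pa = alpha_ps ? 2 : 1;
  const int Pb = beta_ps ? 2 : 1;
  const int nu = n_odors - 1;

  Priors P;
  P.mua_loc = as<double>(prior["mu_alpha_loc"]);
  P.mua_sc = as<double>(prior["mu_alpha_scale"]);
  P.sa_sc = as<double>(prior["sigma_alpha_scale"]);
  P.mub_loc = as<double>(prior["mu_beta_loc"]);
  P.mub_sc = as<double>(prior["mu_beta_scale"]);
  P.sb_sc = as<double>(prior["sigma_beta_scale"]);
  P.v_sc = as<double>(prior["v_scale"]);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N01(0.0, 1.0);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  State st;
  st.mu_a.resize(D.G * Pa);
  st.ls_a.resize(D.G * Pa);
  st.mu_b.resize(D.G * Pb);
  st.ls_b.resize(D.G * Pb);
  st.za.assign(D.K * Pa, 0.0);
  st.zb.assign(D.K * Pb, 0.0);
  st.u.assign(nu, 0.0);
  for (auto& x : st.mu_a) x = 0.0 + 0.3 * N01(rng);
  for (auto& x : st.ls_a) x = std::log(0.3) + 0.1 * N01(rng);
  for (auto& x : st.mu_b) x = P.mub_loc + 0.3 * N01(rng);
  for (auto& x : st.ls_b) x = std::log(0.3) + 0.1 * N01(rng);
  for (auto& x : st.za) x = 0.1 * N01(rng);
  for (auto& x : st.zb) x = 0.1 * N01(rng);
  for (auto& x : st.u) x = 2.0 * N01(rng);

  std::vector<std::vector<int>> by_group(D.G);
  for (int k = 0; k < D.K; ++k) by_group[D.grp[k]].push_back(k);

  std::vector<double> v(n_odors);
  v_from_u(st, n_odors, v);
  std::vector<double> llk(D.K);
  double a2[2], b2[2];
  for (int k = 0; k < D.K; ++k) {
    animal_params(D, st, Pa, Pb, k, a2, b2);
    llk[k] = animal_ll(D, k, a2, b2, v, nullptr);
  }

  // adaptive proposal scales
  std::vector<double> s_anim(D.K, 0.5);
  const int H = 2 * (Pa + Pb);  // hyper components per group
  std::vector<double> s_hyp(D.G * H, 0.5);
  double s_u = 2.0;
  std::vector<int> acc_anim(D.K, 0), acc_hyp(D.G * H, 0);
  int acc_u = 0;
  const int batch = 50;

  const int P_store = 2 * D.G * Pa + 2 * D.G * Pb + D.K * (Pa + Pb) + nu + 1;
  NumericMatrix samples(draws, P_store);
  NumericMatrix pointwise(draws, Ttot);
  std::vector<double> pwbuf(Ttot);

  const int n_iter = warmup + draws;
  const int nz = Pa + Pb;
  std::vector<double> za_old(Pa), zb_old(Pb);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- per-animal local effects, joint proposal ---
    for (int k = 0; k < D.K; ++k) {
      double dprior = 0.0;
      for (int j = 0; j < Pa; ++j) {
        za_old[j] = st.za[k * Pa + j];
        const double zn = za_old[j] + s_anim[k] * N01(rng);
        dprior += 0.5 * (za_old[j] * za_old[j] - zn * zn);
        st.za[k * Pa + j] = zn;
      }
      for (int j = 0; j < Pb; ++j) {
        zb_old[j] = st.zb[k * Pb + j];
        const double zn = zb_old[j] + s_anim[k] * N01(rng);
        dprior += 0.5 * (zb_old[j] * zb_old[j] - zn * zn);
        st.zb[k * Pb + j] = zn;
      }
      animal_params(D, st, Pa, Pb, k, a2, b2);
      const double ll_new = animal_ll(D, k, a2, b2, v, nullptr);
      if (std::log(U01(rng)) < ll_new - llk[k] + dprior) {
        llk[k] = ll_new;
        ++acc_anim[k];
      } else {
        for (int j = 0; j < Pa; ++j) st.za[k * Pa + j] = za_old[j];
        for (int j = 0; j < Pb; ++j) st.zb[k * Pb + j] = zb_old[j];
      }
    }

    // --- group hyperparameters, scalar proposals ---
    for (int g = 0; g < D.G; ++g) {
      for (int h = 0; h < H; ++h) {
        std::vector<double>* vec;
        int idx;
        double dprior;
        if (h < Pa) {
          vec = &st.mu_a; idx = g * Pa + h;
        } else if (h < 2 * Pa) {
          vec = &st.ls_a; idx = g * Pa + (h - Pa);
        } else if (h < 2 * Pa + Pb) {
          vec = &st.mu_b; idx = g * Pb + (h - 2 * Pa);
        } else {
          vec = &st.ls_b; idx = g * Pb + (h - 2 * Pa - Pb);
        }
        const double old = (*vec)[idx];
        const double prop = old + s_hyp[g * H + h] * N01(rng);
        if (h < Pa) dprior = lp_mu(prop, P.mua_loc, P.mua_sc) - lp_mu(old, P.mua_loc, P.mua_sc);
        else if (h < 2 * Pa) dprior = lp_lsigma(prop, P.sa_sc) - lp_lsigma(old, P.sa_sc);
        else if (h < 2 * Pa + Pb) dprior = lp_mu(prop, P.mub_loc, P.mub_sc) - lp_mu(old, P.mub_loc, P.mub_sc);
        else dprior = lp_lsigma(prop, P.sb_sc) - lp_lsigma(old, P.sb_sc);
        (*vec)[idx] = prop;
        double dll = 0.0;
        std::vector<double> ll_new(by_group[g].size());
        for (size_t m = 0; m < by_group[g].size(); ++m) {
          const int k = by_group[g][m];
          animal_params(D, st, Pa, Pb, k, a2, b2);
          ll_new[m] = animal_ll(D, k, a2, b2, v, nullptr);
          dll += ll_new[m] - llk[k];
        }
        if (std::log(U01(rng)) < dll + dprior) {
          for (size_t m = 0; m < by_group[g].size(); ++m)
            llk[by_group[g][m]] = ll_new[m];
          ++acc_hyp[g * H + h];
        } else {
          (*vec)[idx] = old;
        }
      }
    }

    // --- shared initial values, joint proposal ---
    {
      std::vector<double> u_old(st.u);
      double dprior = 0.0;
      for (int i = 0; i < nu; ++i) {
        const double un = st.u[i] + s_u * N01(rng);
        dprior += 0.5 * (st.u[i] * st.u[i] - un * un) / (P.v_sc * P.v_sc);
        st.u[i] = un;
      }
      std::vector<double> v_new(n_odors);
      v_from_u(st, n_odors, v_new);
      std::vector<double> ll_new(D.K);
      double dll = 0.0;
      for (int k = 0; k < D.K; ++k) {
        animal_params(D, st, Pa, Pb, k, a2, b2);
        ll_new[k] = animal_ll(D, k, a2, b2, v_new, nullptr);
        dll += ll_new[k] - llk[k];
      }
      if (std::log(U01(rng)) < dll + dprior) {
        v = v_new;
        llk = ll_new;
        ++acc_u;
      } else {
        st.u = u_old;
      }
    }

    // --- warmup-only adaptation ---
    if (iter <= warmup && iter % batch == 0) {
      const double d = std::min(0.1, 1.0 / std::sqrt((double)iter / batch));
      const double tgt_block = 0.30, tgt_scalar = 0.44;
      for (int k = 0; k < D.K; ++k) {
        s_anim[k] *= std::exp(((double)acc_anim[k] / batch > tgt_block ? d : -d));
        acc_anim[k] = 0;
      }
      for (int j = 0; j < D.G * H; ++j) {
        s_hyp[j] *= std::exp(((double)acc_hyp[j] / batch > tgt_scalar ? d : -d));
        acc_hyp[j] = 0;
      }
      s_u *= std::exp(((double)acc_u / batch > tgt_block ? d : -d));
      acc_u = 0;
    }

    // --- storage ---
    if (iter > warmup) {
      const int row = iter - warmup - 1;
      int col = 0;
      for (double x : st.mu_a) samples(row, col++) = x;
      for (double x : st.ls_a) samples(row, col++) = x;
      for (double x : st.mu_b) samples(row, col++) = x;
      for (double x : st.ls_b) samples(row, col++) = x;
      for (double x : st.za) samples(row, col++) = x;
      for (double x : st.zb) samples(row, col++) = x;
      for (double x : st.u) samples(row, col++) = x;
      double lp = 0.0;
      for (int k = 0; k < D.K; ++k) {
        animal_params(D, st, Pa, Pb, k, a2, b2);
        animal_ll(D, k, a2, b2, v, &pwbuf[D.off[k]]);
        lp += llk[k];
      }
      for (int j = 0; j < D.G * Pa; ++j)
        lp += lp_mu(st.mu_a[j], P.mua_loc, P.mua_sc) + lp_lsigma(st.ls_a[j], P.sa_sc);
      for (int j = 0; j < D.G * Pb; ++j)
        lp += lp_mu(st.mu_b[j], P.mub_loc, P.mub_sc) + lp_lsigma(st.ls_b[j], P.sb_sc);
      for (double z : st.za) lp -= 0.5 * z * z;
      for (double z : st.zb) lp -= 0.5 * z * z;
      for (double x : st.u) lp -= 0.5 * x * x / (P.v_sc * P.v_sc);
      samples(row, col++) = lp;
      for (int t = 0; t < Ttot; ++t) pointwise(row, t) = pwbuf[t];
    }
  }

  return List::create(_["samples"] = samples, _["pointwise"] = pointwise,
                      _["Pa"] = Pa, _["Pb"] = Pb);
}

// Cohort log-likelihood at explicit parameter values; independent entry
// point used for cross-checks and fast posterior summaries.
// alpha, beta: K x 2 matrices (acquisition, test columns, natural scale).
// [[Rcpp::export]]
List cohort_loglik(IntegerVector choice, IntegerVector reward,
                   IntegerVector phase, IntegerVector offsets,
                   NumericMatrix alpha, NumericMatrix beta, NumericVector v,
                   int n_odors, double reward_mag, bool carry_over) {
  CohortData D;
  D.choice.assign(choice.begin(), choice.end());
  D.reward.assign(reward.begin(), reward.end());
  D.phase.assign(phase.begin(), phase.end());
  D.off.assign(offsets.begin(), offsets.end());
  D.K = alpha.nrow();
  D.n_odors = n_odors;
  D.rmag = reward_mag;
  D.carry = carry_over;
  std::vector<double> vv(v.begin(), v.end());
  NumericVector totals(D.K);
  NumericVector pw((int)choice.size());
  double* pwp = REAL(pw);
  for (int k = 0; k < D.K; ++k) {
    double a2[2] = {alpha(k, 0), alpha(k, 1)};
    double b2[2] = {beta(k, 0), beta(k, 1)};
    totals[k] = animal_ll(D, k, a2, b2, vv, pwp + D.off[k]);
  }
  return List::create(_["totals"] = totals, _["pointwise"] = pw);
}
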