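// Metropolis-Hastings kernel of the trans-dimensional sampler.
//
// The particle state is the dipole configuration (sorted distinct vertex
// ids), the moment-scale sigma_q and the cached marginal log-likelihood.
// One sweep applies, per particle, a birth / death / update move targeting
// pi_gamma(N, R, sigma_q) ~ p(y | N, R, sigma_q)^gamma p(N) p(R) p(sigma_q).
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// marginal log-likelihood: y_t ~ N(0, sq^2 G_R G_R' + se^2 I), samples iid
static double logml_idx(const arma::mat& G, const arma::mat& Y,
                        const arma::uvec& vert, int ncomp,
                        double sq, double se) {
  const double se2 = se * se;
  const int m = Y.n_rows, nt = Y.n_cols;
  if (vert.n_elem == 0)
    return -0.5 * (nt * m * std::log(2.0 * M_PI * se2) +
                   arma::accu(Y % Y) / se2);
  arma::uvec cols(vert.n_elem * ncomp);
  for (arma::uword k = 0; k < vert.n_elem; ++k)
    for (int c = 0; c < ncomp; ++c)
      cols[k * ncomp + c] = (vert[k] - 1) * ncomp + c;  // ids are 1-based
  arma::mat Gs = G.cols(cols);
  arma::mat C = (sq * sq) * (Gs * Gs.t());
  C.diag() += se2;
  arma::mat L = arma::chol(C, "lower");
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  arma::mat Z = arma::solve(arma::trimatl(L), Y);
  return -0.5 * (nt * (m * LOG2PI + logdet) + arma::accu(Z % Z));
}

// [[Rcpp::export]]
double cpp_logml(const arma::mat& G, const arma::mat& Y,
                 const arma::uvec& vertices, int ncomp,
                 double sigma_q, double sigma_eps) {
  return logml_idx(G, Y, vertices, ncomp, sigma_q, sigma_eps);
}

// log p(N, R): log pmf[N] + sum log w_v - log e_N(w); -Inf off support
static double log_prior(const arma::uvec& vert, const arma::vec& log_npmf,
                        const arma::vec& log_w, const arma::vec& log_esp,
                        int nmax) {
  const int n = vert.n_elem;
  if (n > nmax) return -arma::datum::inf;
  double lp = log_npmf[n];
  for (int k = 0; k < n; ++k) lp += log_w[vert[k] - 1];
  if (n > 0) lp -= log_esp[n];
  return lp;
}

static int draw_categorical(const arma::vec& cum) {
  const double u = unif_rand() * cum[cum.n_elem - 1];
  return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

static bool contains(const arma::uvec& vert, arma::uword v) {
  return std::binary_search(vert.begin(), vert.end(), v);
}

static arma::uvec insert_sorted(const arma::uvec& vert, arma::uword v) {
  arma::uvec out(vert.n_elem + 1);
  arma::uword i = 0, j = 0;
  while (i < vert.n_elem && vert[i] < v) out[j++] = vert[i++];
  out[j++] = v;
  while (i < vert.n_elem) out[j++] = vert[i++];
  return out;
}

// neighbor-kernel transition probability v -> u (0 if u not a neighbor of v)
static double nb_prob(const arma::ivec& off, const arma::ivec& ids,
                      const arma::vec& probs, int v, int u) {
  for (int k = off[v - 1]; k < off[v]; ++k)
    if (ids[k] == u) return probs[k];
  return 0.0;
}

// One Metropolis-Hastings sweep over all particles (moves_each moves per
// particle). Modifies nothing in place; returns the updated state and
// per-move-type attempt/acceptance counts.
// [[Rcpp::export]]
List cpp_sweep(List vertices_list, arma::vec sigma_q, arma::vec logml,
               const arma::mat& G, const arma::mat& Y, int ncomp,
               double sigma_eps, double gamma,
               const arma::vec& log_npmf, const arma::vec& log_esp,
               const arma::vec& log_w, const arma::vec& w_cum, int nmax,
               const arma::ivec& nb_off, const arma::ivec& nb_ids,
               const arma::vec& nb_probs, const arma::vec& nb_cum,
               bool hyper, double sq_min, double range_factor,
               double walk_scale, const arma::vec& move_probs,
               int moves_each) {
  const int I = vertices_list.size();
  const double pb = move_probs[0], pd = move_probs[1];
  const double sq_hi = sq_min * range_factor;
  arma::imat attempts(3, 1, arma::fill::zeros);
  arma::imat accepts(3, 1, arma::fill::zeros);
  List out_vert(I);

  for (int i = 0; i < I; ++i) {
    IntegerVector vi = vertices_list[i];
    arma::uvec vert = as<arma::uvec>(vi);
    double sq = sigma_q[i], lml = logml[i];
    double lp = log_prior(vert, log_npmf, log_w, log_esp, nmax);

    for (int s = 0; s < moves_each; ++s) {
      const double u_move = unif_rand();
      const int n = vert.n_elem;

      if (u_move < pb) {                                    // ---- birth
        attempts(0, 0)++;
        if (n >= nmax) continue;
        const int v = draw_categorical(w_cum) + 1;
        if (contains(vert, (arma::uword)v)) continue;
        arma::uvec prop = insert_sorted(vert, (arma::uword)v);
        double lp_new = log_prior(prop, log_npmf, log_w, log_esp, nmax);
        if (!std::isfinite(lp_new)) continue;
        double lml_new = logml_idx(G, Y, prop, ncomp, sq, sigma_eps);
        double logA = gamma * (lml_new - lml) + (lp_new - lp)
          + std::log(pd) - std::log((double)(n + 1))
          - std::log(pb) - log_w[v - 1];
        if (std::log(unif_rand()) < logA) {
          vert = prop; lml = lml_new; lp = lp_new; accepts(0, 0)++;
        }
      } else if (u_move < pb + pd) {                        // ---- death
        attempts(1, 0)++;
        if (n == 0) continue;
        const int j = std::min((int)(unif_rand() * n), n - 1);
        const int v = vert[j];
        arma::uvec prop = vert;
        prop.shed_row(j);
        double lp_new = log_prior(prop, log_npmf, log_w, log_esp, nmax);
        double lml_new = logml_idx(G, Y, prop, ncomp, sq, sigma_eps);
        double logA = gamma * (lml_new - lml) + (lp_new - lp)
          + std::log(pb) + log_w[v - 1]
          - std::log(pd) + std::log((double)n);
        if (std::log(unif_rand()) < logA) {
          vert = prop; lml = lml_new; lp = lp_new; accepts(1, 0)++;
        }
      } else {                                              // ---- update
        attempts(2, 0)++;
        if (n == 0) {
          // only the moment scale can move; log-uniform prior and the
          // log-normal walk Jacobian cancel exactly inside the support
          if (!hyper) continue;
          double sq_new = std::exp(std::log(sq) + walk_scale * norm_rand());
          if (sq_new < sq_min || sq_new > sq_hi) continue;
          sq = sq_new;  // logA = 0: always accept (n = 0 likelihood has no sq)
          accepts(2, 0)++;
          continue;
        }
        const int j = std::min((int)(unif_rand() * n), n - 1);
        const int v = vert[j];
        const double u_nb = unif_rand() *
          (nb_cum[nb_off[v] - 1] - (nb_off[v - 1] > 0 ? nb_cum[nb_off[v - 1] - 1] : 0.0));
        double base = (nb_off[v - 1] > 0 ? nb_cum[nb_off[v - 1] - 1] : 0.0);
        int k = (int)(std::upper_bound(nb_cum.begin() + nb_off[v - 1],
                                       nb_cum.begin() + nb_off[v],
                                       base + u_nb) - nb_cum.begin());
        if (k >= nb_off[v]) k = nb_off[v] - 1;
        const int v_new = nb_ids[k];
        if (contains(vert, (arma::uword)v_new)) continue;
        double sq_new = sq;
        double log_jac = 0.0;
        if (hyper) {
          sq_new = std::exp(std::log(sq) + walk_scale * norm_rand());
          if (sq_new < sq_min || sq_new > sq_hi) continue;
          // hyper-prior ratio (sq/sq_new) times walk Jacobian (sq_new/sq) = 1
        }
        arma::uvec prop = vert;
        prop.shed_row(j);
        prop = insert_sorted(prop, (arma::uword)v_new);
        double lp_new = log_prior(prop, log_npmf, log_w, log_esp, nmax);
        if (!std::isfinite(lp_new)) continue;
        double q_fwd = nb_prob(nb_off, nb_ids, nb_probs, v, v_new);
        double q_rev = nb_prob(nb_off, nb_ids, nb_probs, v_new, v);
        if (q_rev == 0.0) continue;
        double lml_new = logml_idx(G, Y, prop, ncomp, sq_new, sigma_eps);
        double logA = gamma * (lml_new - lml) + (lp_new - lp)
          + std::log(q_rev) - std::log(q_fwd) + log_jac;
        if (std::log(unif_rand()) < logA) {
          vert = prop; sq = sq_new; lml = lml_new; lp = lp_new;
          accepts(2, 0)++;
        }
      }
    }
    out_vert[i] = wrap(arma::conv_to<std::vector<int>>::from(vert));
    sigma_q[i] = sq;
    logml[i] = lml;
  }
  return List::create(_["vertices"] = out_vert, _["sigma_q"] = sigma_q,
                      _["logml"] = logml,
                      _["attempts"] = attempts.col(0),
                      _["accepts"] = accepts.col(0));
}
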