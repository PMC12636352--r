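// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>

using namespace Rcpp;

// standard normal via Box-Muller over R's uniform stream: much cheaper than
// the inversion sampler and still fully reproducible under set.seed()
static inline double fast_norm() {
  double u1 = unif_rand(), u2 = unif_rand();
  while (u1 <= 0) u1 = unif_rand();
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// Gibbs sampler for the spike-and-slab regression
//   y = C alpha + X beta + eps,  eps ~ N(0, de2 I)
//   beta_j ~ (1-gamma_j) N(0, d02) + gamma_j N(0, d12)
//   gamma_j ~ Bern(pi), pi ~ Beta(a_pi, b_pi)
//   1/d12 ~ Gamma(a1, b1), 1/de2 ~ Gamma(ae, be), alpha flat.
// gamma_j is drawn with beta_j integrated out under its two-component prior,
// then beta_j from the conjugate normal conditional. X is passed in
// compressed-sparse-column form (count matrices are sparse after the
// prevalence filter); covariates may be a dense matrix or, when every row is
// a one-hot indicator (e.g. per-pangene baselines), a group index vector
// with O(n) updates. Uses R's RNG, so draws are reproducible under
// set.seed().
// [[Rcpp::export]]
List cpp_gibbs(const arma::vec& y, const arma::mat& C,
               const IntegerVector& c_group, int n_groups,
               const IntegerVector& Xp, const IntegerVector& Xi,
               const NumericVector& Xx, int p,
               double d02, double a_pi, double b_pi, double a1, double b1,
               double ae, double be, int iters, int burn_in, int thin,
               bool fix_pi, double pi_fixed, bool fix_d12, double d12_fixed,
               bool fix_de2, double de2_fixed, bool random_scan) {
  RNGScope scope;
  const int n = (int)y.n_elem;
  const bool grouped = n_groups > 0;  // indicator-covariate fast path
  const int pc = grouped ? n_groups : (int)C.n_cols;
  if (iters <= burn_in) stop("iters must exceed burn_in");
  if (thin < 1) stop("thin must be >= 1");

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int t = Xp[j]; t < Xp[j + 1]; ++t) s += Xx[t] * Xx[t];
    xtx[j] = s;
  }

  // compact internal copy of X: the sweep is memory-bandwidth-bound, so
  // 16-bit row indices (when n allows) and float values halve the traffic
  const R_xlen_t nnz = Xi.size();
  const bool small_rows = n < 65536;
  std::vector<uint16_t> idx16;
  std::vector<int> idx32;
  std::vector<float> vals(nnz);
  for (R_xlen_t t = 0; t < nnz; ++t) vals[t] = (float)Xx[t];
  if (small_rows) {
    idx16.resize(nnz);
    for (R_xlen_t t = 0; t < nnz; ++t) idx16[t] = (uint16_t)Xi[t];
  } else {
    idx32.resize(nnz);
    for (R_xlen_t t = 0; t < nnz; ++t) idx32[t] = Xi[t];
  }

  arma::mat CtC_chol;
  arma::vec group_n;
  if (grouped) {
    group_n.zeros(pc);
    for (int i = 0; i < n; ++i) {
      int g = c_group[i];
      if (g < 0 || g >= pc) stop("covariate group index out of range");
      group_n[g] += 1;
    }
    if (arma::any(group_n == 0)) stop("empty covariate group");
  } else if (pc > 0) {
    arma::mat CtC = C.t() * C;
    if (!arma::chol(CtC_chol, CtC)) stop("covariate matrix C is rank deficient");
  }

  arma::vec beta(p, arma::fill::zeros);
  arma::ivec gam(p, arma::fill::zeros);
  arma::vec alpha(pc, arma::fill::zeros);
  double pi_cur = fix_pi ? pi_fixed : 0.1;
  double d12 = fix_d12 ? d12_fixed : arma::var(y) + 1e-8;
  double de2 = fix_de2 ? de2_fixed : arma::var(y) + 1e-8;
  arma::vec r = y;

  // start alpha at its least-squares value
  auto draw_alpha = [&](bool with_noise) {
    if (pc == 0) return;
    if (grouped) {
      arma::vec gsum(pc, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        r[i] += alpha[c_group[i]];
        gsum[c_group[i]] += r[i];
      }
      for (int g = 0; g < pc; ++g) {
        double mean = gsum[g] / group_n[g];
        alpha[g] = with_noise ? mean + std::sqrt(de2 / group_n[g]) * fast_norm()
                              : mean;
      }
      for (int i = 0; i < n; ++i) r[i] -= alpha[c_group[i]];
    } else {
      r += C * alpha;
      arma::vec t = C.t() * r;
      arma::vec mean = arma::solve(arma::trimatu(CtC_chol),
                                   arma::solve(arma::trimatl(CtC_chol.t()), t));
      if (with_noise) {
        arma::vec z(pc);
        for (int i = 0; i < pc; ++i) z[i] = fast_norm();
        alpha = mean + std::sqrt(de2) * arma::solve(arma::trimatu(CtC_chol), z);
      } else alpha = mean;
      r -= C * alpha;
    }
  };
  draw_alpha(false);

  const int n_keep = (iters - burn_in + thin - 1) / thin;
  arma::vec pip(p, arma::fill::zeros), beta_sum(p, arma::fill::zeros);
  arma::vec beta_slab_sum(p, arma::fill::zeros);
  arma::ivec slab_n(p, arma::fill::zeros);
  arma::vec alpha_sum(pc, arma::fill::zeros);
  NumericVector tr_pi(n_keep), tr_d12(n_keep), tr_de2(n_keep);
  IntegerVector tr_size(n_keep);
  int kept = 0;

  std::vector<int> order(p);
  for (int j = 0; j < p; ++j) order[j] = j;

  for (int it = 0; it < iters; ++it) {
    if (random_scan) {
      for (int j = p - 1; j > 0; --j) {
        int u = (int)std::floor(unif_rand() * (j + 1));
        std::swap(order[j], order[u]);
      }
    }
    const double log_odds_pi = std::log(pi_cur) - std::log1p(-pi_cur);
    // the s-dependent pieces of the marginal-likelihood ratio and of the
    // conditional beta draw are shared by all columns with equal x'x
    // (counts are integers, so collisions are exact); memoize per sweep
    struct STerms { double log_ratio, quad_coef, pv1, pv0, sd1, sd0; };
    std::unordered_map<long long, STerms> cache;
    cache.reserve(512);
    auto compute_terms = [&](double s) {
      STerms t;
      const double q1 = de2 + d12 * s, q0 = de2 + d02 * s;
      t.log_ratio = 0.5 * std::log(q0 / q1);
      t.quad_coef = (d12 / q1 - d02 / q0) / (2.0 * de2);
      t.pv1 = 1.0 / (s / de2 + 1.0 / d12);
      t.pv0 = 1.0 / (s / de2 + 1.0 / d02);
      t.sd1 = std::sqrt(t.pv1);
      t.sd0 = std::sqrt(t.pv0);
      return t;
    };
    auto terms_for = [&](double s) -> STerms {
      long long key = (long long)s;
      if ((double)key != s) return compute_terms(s);  // non-integer x'x: no cache
      auto it = cache.find(key);
      if (it == cache.end()) it = cache.emplace(key, compute_terms(s)).first;
      return it->second;
    };
    auto sweep_cols = [&](auto* idx) {
      double* rp = r.memptr();
      for (int jj = 0; jj < p; ++jj) {
        const int j = order[jj];
        const double s = xtx[j];
        const STerms tm = terms_for(s);
        double dot = 0;
        const int t0 = Xp[j], t1 = Xp[j + 1];
        for (int t = t0; t < t1; ++t) dot += (double)vals[t] * rp[idx[t]];
        const double b = dot + beta[j] * s;  // x_j' (r + x_j beta_j)
        const double lo = log_odds_pi + tm.log_ratio + b * b * tm.quad_coef;
        int g;
        if (lo > 35.0) g = 1;
        else if (lo < -35.0) g = 0;
        else g = (unif_rand() < 1.0 / (1.0 + std::exp(-lo))) ? 1 : 0;
        const double post_var = g ? tm.pv1 : tm.pv0;
        const double post_sd = g ? tm.sd1 : tm.sd0;
        const double bj = post_var * b / de2 + post_sd * fast_norm();
        const double diff = beta[j] - bj;
        if (diff != 0.0)
          for (int t = t0; t < t1; ++t) rp[idx[t]] += (double)vals[t] * diff;
        gam[j] = g;
        beta[j] = bj;
      }
    };
    if (small_rows) sweep_cols(idx16.data()); else sweep_cols(idx32.data());
    draw_alpha(true);
    const int m = (int)arma::accu(gam);
    if (!fix_pi) {
      pi_cur = R::rbeta(a_pi + m, b_pi + p - m);
      if (pi_cur <= 0) pi_cur = 1e-12;
      if (pi_cur >= 1) pi_cur = 1 - 1e-12;
    }
    if (!fix_d12) {
      double ssb = 0;
      for (int j = 0; j < p; ++j) if (gam[j]) ssb += beta[j] * beta[j];
      d12 = 1.0 / R::rgamma(a1 + 0.5 * m, 1.0 / (b1 + 0.5 * ssb));
    }
    const double rss = arma::dot(r, r);
    if (!std::isfinite(rss)) stop("residual sum of squares diverged; check inputs/scaling");
    if (!fix_de2)
      de2 = 1.0 / R::rgamma(ae + 0.5 * n, 1.0 / (be + 0.5 * rss));

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int j = 0; j < p; ++j) {
        if (gam[j]) { pip[j] += 1; beta_slab_sum[j] += beta[j]; slab_n[j] += 1; }
        beta_sum[j] += beta[j];
      }
      alpha_sum += alpha;
      tr_pi[kept] = pi_cur;
      tr_d12[kept] = d12;
      tr_de2[kept] = de2;
      tr_size[kept] = m;
      ++kept;
    }
  }
  pip /= kept;
  beta_sum /= kept;
  arma::vec slab_mean(p);
  for (int j = 0; j < p; ++j)
    slab_mean[j] = slab_n[j] > 0 ? beta_slab_sum[j] / slab_n[j] : NA_REAL;
  alpha_sum /= (kept > 0 ? kept : 1);
  return List::create(_["pip"] = NumericVector(pip.begin(), pip.end()),
                      _["beta_mean"] = NumericVector(beta_sum.begin(), beta_sum.end()),
                      _["beta_slab_mean"] = NumericVector(slab_mean.begin(), slab_mean.end()),
                      _["alpha_mean"] = NumericVector(alpha_sum.begin(), alpha_sum.end()),
                      _["trace_pi"] = tr_pi, _["trace_delta1_sq"] = tr_d12,
                      _["trace_deltae_sq"] = tr_de2, _["trace_size"] = tr_size,
                      _["n_kept"] = kept);
}
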