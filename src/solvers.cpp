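// Gauss-Seidel solvers with residual update and single-site Gibbs samplers
// for the pedigree ("animal") model and the ridge-regression marker model.
// All random draws go through R's RNG so that set.seed() in R makes every
// chain exactly reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Plain Gauss-Seidel on a dense symmetric positive-definite system C x = b.
// Stops when the largest coordinate update in a sweep falls below tol.
// [[Rcpp::export(name = ".gs_dense_cpp")]]
List gs_dense_cpp(const arma::mat& C, const arma::vec& b,
                  double tol = 1e-8, int max_sweeps = 1000) {
  const int p = C.n_rows;
  arma::vec x(p, arma::fill::zeros);
  // residual-update form: keep r = b - C x
  arma::vec r = b;
  double delta = R_PosInf;
  int sweep = 0;
  while (sweep < max_sweeps) {
    ++sweep;
    delta = 0.0;
    for (int i = 0; i < p; ++i) {
      double cii = C(i, i);
      if (cii <= 0.0) stop("non-positive diagonal in coefficient matrix");
      double xnew = x[i] + r[i] / cii;
      double d = xnew - x[i];
      if (d != 0.0) {
        r -= C.col(i) * d;
        x[i] = xnew;
        double ad = std::fabs(d);
        if (ad > delta) delta = ad;
      }
    }
    if (delta < tol) break;
  }
  return List::create(_["solution"] = x,
                      _["sweeps"] = sweep,
                      _["converged"] = (delta < tol),
                      _["last_delta"] = delta);
}

// Gauss-Seidel with residual update for the ridge system
//   [1'1      1'Z   ] [mu   ]   [1'y]
//   [Z'1  Z'Z + l I ] [alpha] = [Z'y]
// operating directly on the n x m data matrix Z (never forming Z'Z).
// e is kept equal to y - mu - Z alpha throughout.
// [[Rcpp::export(name = ".gs_ridge_cpp")]]
List gs_ridge_cpp(const arma::mat& Z, const arma::vec& y, double lambda,
                  double tol = 1e-8, int max_sweeps = 1000) {
  const int n = Z.n_rows, m = Z.n_cols;
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec e = y;
  double mu = 0.0;
  arma::vec czz(m);
  for (int j = 0; j < m; ++j) czz[j] = arma::dot(Z.col(j), Z.col(j));
  double delta = R_PosInf;
  int sweep = 0;
  while (sweep < max_sweeps) {
    ++sweep;
    delta = 0.0;
    // intercept (unpenalized)
    double mu_new = mu + arma::mean(e);
    double dmu = mu_new - mu;
    if (dmu != 0.0) { e -= dmu; mu = mu_new; delta = std::fabs(dmu); }
    for (int j = 0; j < m; ++j) {
      double cjj = czz[j] + lambda;
      double rhs = arma::dot(Z.col(j), e) + czz[j] * alpha[j];
      double anew = rhs / cjj;
      double d = anew - alpha[j];
      if (d != 0.0) {
        e -= Z.col(j) * d;
        alpha[j] = anew;
        double ad = std::fabs(d);
        if (ad > delta) delta = ad;
      }
    }
    if (delta < tol) break;
  }
  return List::create(_["mu"] = mu, _["alpha"] = alpha,
                      _["sweeps"] = sweep,
                      _["converged"] = (delta < tol),
                      _["residuals"] = e);
}

// Gibbs sampler for the marker (ridge-regression) model
//   y = 1 mu + Z alpha + e,  alpha ~ N(0, I s2a),  e ~ N(0, I s2e)
// Flat priors on variances implemented as scaled-inverse-chi-square with
// nu = -2, scale 0, so the full conditional is SS / chisq(df - 2).
// Location effects use single-site updates with residual update.
// [[Rcpp::export(name = ".gibbs_ridge_cpp")]]
List gibbs_ridge_cpp(const arma::mat& Z, const arma::vec& y,
                     int n_iter, int burn_in, int thin) {
  const int n = Z.n_rows, m = Z.n_cols;
  if (n < 3) stop("need at least 3 observations");
  if (m < 3) stop("need at least 3 markers for flat-prior variance draws");
  RNGScope scope;

  arma::vec czz(m);
  for (int j = 0; j < m; ++j) czz[j] = arma::dot(Z.col(j), Z.col(j));
  double vy = arma::var(y);
  if (vy <= 0.0) stop("response has zero variance");
  // crude initial split of the phenotypic variance
  double mean_css = arma::mean(czz) * m / (double)n; // ~ sum_k 2 p q
  if (mean_css <= 0.0) mean_css = 1.0;
  double s2a = 0.5 * vy / mean_css;
  double s2e = 0.5 * vy;

  double mu = arma::mean(y);
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec e = y - mu;

  int n_keep = n_iter - burn_in;
  arma::vec alpha_sum(m, arma::fill::zeros);
  double mu_sum = 0.0, s2a_sum = 0.0, s2e_sum = 0.0;
  std::vector<double> tr_it, tr_s2a, tr_s2e, tr_mu;

  for (int it = 1; it <= n_iter; ++it) {
    // mu | rest
    double emean = arma::mean(e);
    double mu_new = mu + emean + norm_rand() * std::sqrt(s2e / n);
    e -= (mu_new - mu);
    mu = mu_new;
    // alpha_j | rest
    double lambda = s2e / s2a;
    for (int j = 0; j < m; ++j) {
      if (czz[j] == 0.0) { // monomorphic: conditional is the prior
        alpha[j] = norm_rand() * std::sqrt(s2a);
        continue;
      }
      double cjj = czz[j] + lambda;
      double rhs = arma::dot(Z.col(j), e) + czz[j] * alpha[j];
      double anew = rhs / cjj + norm_rand() * std::sqrt(s2e / cjj);
      double d = anew - alpha[j];
      e -= Z.col(j) * d;
      alpha[j] = anew;
    }
    // variances | rest (flat priors, nu = -2)
    s2a = arma::dot(alpha, alpha) / Rf_rchisq((double)(m - 2));
    s2e = arma::dot(e, e) / Rf_rchisq((double)(n - 2));

    if (it > burn_in) {
      alpha_sum += alpha;
      mu_sum += mu; s2a_sum += s2a; s2e_sum += s2e;
      if ((it - burn_in) % thin == 0) {
        tr_it.push_back(it); tr_s2a.push_back(s2a);
        tr_s2e.push_back(s2e); tr_mu.push_back(mu);
      }
    }
  }
  return List::create(
    _["mu"] = mu_sum / n_keep,
    _["alpha"] = alpha_sum / n_keep,
    _["sigma2_a"] = s2a_sum / n_keep,
    _["sigma2_e"] = s2e_sum / n_keep,
    _["trace"] = DataFrame::create(_["iteration"] = tr_it, _["mu"] = tr_mu,
                                   _["sigma2_a"] = tr_s2a,
                                   _["sigma2_e"] = tr_s2e));
}

// Gibbs sampler for the individual-tree (animal) model
//   y = X beta + S p + T u + e
//   p ~ N(0, I s2p), u ~ N(0, A s2u), e ~ N(0, I s2e)
// X: n x pfix dense fixed-effect design (full column rank).
// block: 1-based block index per observation (0 = no block effect).
// ind:   1-based position of each observation's individual in the pedigree.
// Ainv:  dense inverse numerator relationship matrix (q x q).
// The running vector w = Ainv * u is maintained incrementally so each
// iteration costs O(q^2) for the pedigree part.
// [[Rcpp::export(name = ".gibbs_animal_cpp")]]
List gibbs_animal_cpp(const arma::mat& X, const IntegerVector& block,
                      int n_blocks, const IntegerVector& ind,
                      const arma::mat& Ainv, const arma::vec& y,
                      int n_iter, int burn_in, int thin) {
  const int n = y.n_elem, pfix = X.n_cols, q = Ainv.n_rows;
  if (n < 3) stop("need at least 3 observations");
  const bool use_block = (n_blocks > 0);
  if (use_block && n_blocks < 3)
    stop("need at least 3 blocks for flat-prior variance draws (or none)");
  RNGScope scope;

  arma::vec cxx(pfix);
  for (int k = 0; k < pfix; ++k) cxx[k] = arma::dot(X.col(k), X.col(k));
  // per-individual observation lists
  std::vector< std::vector<int> > obs_of(q);
  for (int i = 0; i < n; ++i) obs_of[ind[i] - 1].push_back(i);
  std::vector< std::vector<int> > obs_blk(use_block ? n_blocks : 0);
  if (use_block)
    for (int i = 0; i < n; ++i) obs_blk[block[i] - 1].push_back(i);

  double vy = arma::var(y);
  if (vy <= 0.0) stop("response has zero variance");
  double s2u = 0.4 * vy, s2e = 0.5 * vy, s2p = use_block ? 0.1 * vy : 0.0;

  arma::vec beta(pfix, arma::fill::zeros);
  arma::vec bp(use_block ? n_blocks : 1, arma::fill::zeros);
  arma::vec u(q, arma::fill::zeros);
  arma::vec w(q, arma::fill::zeros); // Ainv * u
  arma::vec e = y;

  int n_keep = n_iter - burn_in;
  arma::vec u_sum(q, arma::fill::zeros), beta_sum(pfix, arma::fill::zeros);
  arma::vec bp_sum(bp.n_elem, arma::fill::zeros);
  double s2u_sum = 0, s2e_sum = 0, s2p_sum = 0;
  std::vector<double> tr_it, tr_s2u, tr_s2e, tr_s2p;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects (flat prior)
    for (int k = 0; k < pfix; ++k) {
      double rhs = arma::dot(X.col(k), e) + cxx[k] * beta[k];
      double bnew = rhs / cxx[k] + norm_rand() * std::sqrt(s2e / cxx[k]);
      double d = bnew - beta[k];
      if (d != 0.0) { e -= X.col(k) * d; beta[k] = bnew; }
    }
    // block effects
    if (use_block) {
      double lp = s2e / s2p;
      for (int b = 0; b < n_blocks; ++b) {
        const std::vector<int>& ob = obs_blk[b];
        double nb = (double)ob.size();
        double cbb = nb + lp;
        double se = 0.0;
        for (size_t t = 0; t < ob.size(); ++t) se += e[ob[t]];
        double rhs = se + nb * bp[b];
        double bnew = rhs / cbb + norm_rand() * std::sqrt(s2e / cbb);
        double d = bnew - bp[b];
        for (size_t t = 0; t < ob.size(); ++t) e[ob[t]] -= d;
        bp[b] = bnew;
      }
    }
    // additive genetic effects
    double lu = s2e / s2u;
    for (int i = 0; i < q; ++i) {
      const std::vector<int>& oi = obs_of[i];
      double ni = (double)oi.size();
      double aii = Ainv(i, i);
      double cii = ni + lu * aii;
      double se = 0.0;
      for (size_t t = 0; t < oi.size(); ++t) se += e[oi[t]];
      double rhs = se + ni * u[i] - lu * (w[i] - aii * u[i]);
      double unew = rhs / cii + norm_rand() * std::sqrt(s2e / cii);
      double d = unew - u[i];
      if (d != 0.0) {
        for (size_t t = 0; t < oi.size(); ++t) e[oi[t]] -= d;
        w += Ainv.col(i) * d;
        u[i] = unew;
      }
    }
    // variances (flat priors, nu = -2)
    s2u = arma::dot(u, w) / Rf_rchisq((double)(q - 2));
    if (use_block)
      s2p = arma::dot(bp, bp) / Rf_rchisq((double)(n_blocks - 2));
    s2e = arma::dot(e, e) / Rf_rchisq((double)(n - 2));

    if (it > burn_in) {
      u_sum += u; beta_sum += beta; bp_sum += bp;
      s2u_sum += s2u; s2e_sum += s2e; s2p_sum += s2p;
      if ((it - burn_in) % thin == 0) {
        tr_it.push_back(it); tr_s2u.push_back(s2u);
        tr_s2p.push_back(s2p); tr_s2e.push_back(s2e);
      }
    }
  }
  return List::create(
    _["beta"] = beta_sum / n_keep,
    _["block_effects"] = bp_sum / n_keep,
    _["u"] = u_sum / n_keep,
    _["sigma2_u"] = s2u_sum / n_keep,
    _["sigma2_p"] = use_block ? s2p_sum / n_keep : NA_REAL,
    _["sigma2_e"] = s2e_sum / n_keep,
    _["trace"] = DataFrame::create(_["iteration"] = tr_it,
                                   _["sigma2_u"] = tr_s2u,
                                   _["sigma2_p"] = tr_s2p,
                                   _["sigma2_e"] = tr_s2e));
}
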