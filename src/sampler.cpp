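// Gibbs sampler for the dyadic probit (threshold) mixed model.
//
// Liability:  l_i = x_i' beta + a_s (eta_s[ai] + eta_s[bi])
//                          + a_p (eta_p[ai] + eta_p[bi]) + e_i,  e ~ N(0, 1)
// y_i = 1{l_i > 0}.  Residual variance fixed at 1.
//
// Parameter-expanded (working-parameter) representation of each random
// effect: u = alpha * eta with eta ~ N(0, s2_eta K), alpha ~ N(am, aV),
// s2_eta ~ IW(V, nu) (univariate, i.e. scaled inverse-chi-square).  The
// reported variance component is alpha^2 * s2_eta; u is alpha * eta.
// K = I for the species effect, K = A (phylogenetic covariance) for the
// phylogenetic effect, supplied through its inverse Ainv.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// N(0,1) truncated to (lo, +inf) for lo standardized; inverse-CDF in the
// body, Robert (1995) exponential rejection in the deep tail.
static double rtruncnorm_lower(double lo) {
  if (lo < 5.0) {
    double plo = R::pnorm(lo, 0.0, 1.0, 1, 0);
    double u = R::runif(plo, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  double lambda = 0.5 * (lo + std::sqrt(lo * lo + 4.0));
  for (;;) {
    double z = lo + R::exp_rand() / lambda;
    double rho = std::exp(-0.5 * (z - lambda) * (z - lambda));
    if (R::unif_rand() < rho) return z;
  }
}

// draw from liability ~ N(mu, 1) truncated to l > 0 (pos) or l < 0
static double draw_liability(double mu, bool pos) {
  if (pos) return mu + rtruncnorm_lower(-mu);
  return -(-mu + rtruncnorm_lower(mu));
}

// [[Rcpp::export(name = ".gibbs_probit_mm")]]
List gibbs_probit_mm(const arma::ivec& y,
                     const arma::mat& X,
                     const arma::ivec& ia,       // 0-based species index, parent a
                     const arma::ivec& ib,       // parent b
                     const arma::mat& Ainv,      // S x S (ignored if !use_phylo)
                     int S,
                     bool use_species, bool use_phylo,
                     double vB,
                     double nu_s, double V_s, double am_s, double aV_s,
                     double nu_p, double V_p, double am_p, double aV_p,
                     int n_iter, int burnin, int thin) {
  const int n = y.n_elem, p = X.n_cols;
  const int qs = use_species ? S : 0;
  const int qp = use_phylo ? S : 0;
  const int q = p + qs + qp;

  // fixed cross-products
  arma::mat XtX = X.t() * X;
  arma::mat Z(n, S, arma::fill::zeros);
  if (use_species || use_phylo) {
    for (int i = 0; i < n; ++i) { Z(i, ia[i]) += 1.0; Z(i, ib[i]) += 1.0; }
  }
  arma::mat XtZ, ZtZ;
  if (qs + qp > 0) { XtZ = X.t() * Z; ZtZ = Z.t() * Z; }

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::vec eta_s(S, arma::fill::zeros), eta_p(S, arma::fill::zeros);
  double alpha_s = 1.0, alpha_p = 1.0, s2es = V_s, s2ep = V_p;
  arma::vec l(n, arma::fill::zeros);

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat beta_draws(n_keep, p);
  arma::mat var_draws(n_keep, 2, arma::fill::zeros);  // sigma2_s, sigma2_p
  arma::vec us_mean(S, arma::fill::zeros), up_mean(S, arma::fill::zeros);
  int kept = 0;
  bool diverged = false;

  arma::mat C(q, q);
  arma::vec rhs(q), theta(q), z(q), mu_l(n);

  for (int it = 1; it <= n_iter; ++it) {
    // 1. liabilities
    mu_l = X * beta;
    if (qs) for (int i = 0; i < n; ++i)
      mu_l[i] += alpha_s * (eta_s[ia[i]] + eta_s[ib[i]]);
    if (qp) for (int i = 0; i < n; ++i)
      mu_l[i] += alpha_p * (eta_p[ia[i]] + eta_p[ib[i]]);
    if (!mu_l.is_finite())
      stop("non-finite liability mean at iteration %d", it);
    if (arma::abs(mu_l).max() > 50.0) diverged = true;
    for (int i = 0; i < n; ++i) l[i] = draw_liability(mu_l[i], y[i] == 1);

    // 2. joint (beta, eta_s, eta_p) from the mixed-model equations
    C.zeros();
    C.submat(0, 0, p - 1, p - 1) = XtX;
    C.submat(0, 0, p - 1, p - 1).diag() += 1.0 / vB;
    int off_s = p, off_p = p + qs;
    if (qs) {
      C.submat(0, off_s, p - 1, off_s + S - 1) = alpha_s * XtZ;
      C.submat(off_s, 0, off_s + S - 1, p - 1) = alpha_s * XtZ.t();
      C.submat(off_s, off_s, off_s + S - 1, off_s + S - 1) =
        alpha_s * alpha_s * ZtZ;
      C.submat(off_s, off_s, off_s + S - 1, off_s + S - 1).diag() += 1.0 / s2es;
    }
    if (qp) {
      C.submat(0, off_p, p - 1, off_p + S - 1) = alpha_p * XtZ;
      C.submat(off_p, 0, off_p + S - 1, p - 1) = alpha_p * XtZ.t();
      C.submat(off_p, off_p, off_p + S - 1, off_p + S - 1) =
        alpha_p * alpha_p * ZtZ + Ainv / s2ep;
      if (qs) {
        C.submat(off_s, off_p, off_s + S - 1, off_p + S - 1) =
          alpha_s * alpha_p * ZtZ;
        C.submat(off_p, off_s, off_p + S - 1, off_s + S - 1) =
          alpha_s * alpha_p * ZtZ;
      }
    }
    rhs.subvec(0, p - 1) = X.t() * l;
    if (qs + qp > 0) {
      arma::vec Ztl(S, arma::fill::zeros);
      for (int i = 0; i < n; ++i) { Ztl[ia[i]] += l[i]; Ztl[ib[i]] += l[i]; }
      if (qs) rhs.subvec(off_s, off_s + S - 1) = alpha_s * Ztl;
      if (qp) rhs.subvec(off_p, off_p + S - 1) = alpha_p * Ztl;
    }
    arma::mat U;
    if (!arma::chol(U, C))
      stop("mixed-model coefficient matrix not positive definite at iteration %d", it);
    // theta = C^{-1} rhs + U^{-1} z,  z ~ N(0, I)
    arma::vec tmp = arma::solve(arma::trimatl(U.t()), rhs);
    arma::vec mean_theta = arma::solve(arma::trimatu(U), tmp);
    for (int j = 0; j < q; ++j) z[j] = R::norm_rand();
    theta = mean_theta + arma::solve(arma::trimatu(U), z);
    beta = theta.subvec(0, p - 1);
    if (qs) eta_s = theta.subvec(off_s, off_s + S - 1);
    if (qp) eta_p = theta.subvec(off_p, off_p + S - 1);

    // 3. working scale parameters alpha (joint if both components present)
    if (qs + qp > 0) {
      arma::vec r = l - X * beta;
      arma::vec vs(n, arma::fill::zeros), vp(n, arma::fill::zeros);
      if (qs) for (int i = 0; i < n; ++i) vs[i] = eta_s[ia[i]] + eta_s[ib[i]];
      if (qp) for (int i = 0; i < n; ++i) vp[i] = eta_p[ia[i]] + eta_p[ib[i]];
      if (qs && qp) {
        arma::mat P(2, 2);
        P(0, 0) = arma::dot(vs, vs) + 1.0 / aV_s;
        P(1, 1) = arma::dot(vp, vp) + 1.0 / aV_p;
        P(0, 1) = P(1, 0) = arma::dot(vs, vp);
        arma::vec b2(2);
        b2[0] = arma::dot(vs, r) + am_s / aV_s;
        b2[1] = arma::dot(vp, r) + am_p / aV_p;
        arma::mat U2 = arma::chol(P);
        arma::vec m2 = arma::solve(arma::trimatu(U2),
                        arma::solve(arma::trimatl(U2.t()), b2));
        arma::vec z2(2);
        z2[0] = R::norm_rand(); z2[1] = R::norm_rand();
        arma::vec a2 = m2 + arma::solve(arma::trimatu(U2), z2);
        alpha_s = a2[0]; alpha_p = a2[1];
      } else if (qs) {
        double prec = arma::dot(vs, vs) + 1.0 / aV_s;
        double m1 = (arma::dot(vs, r) + am_s / aV_s) / prec;
        alpha_s = m1 + R::norm_rand() / std::sqrt(prec);
      } else {
        double prec = arma::dot(vp, vp) + 1.0 / aV_p;
        double m1 = (arma::dot(vp, r) + am_p / aV_p) / prec;
        alpha_p = m1 + R::norm_rand() / std::sqrt(prec);
      }
    }

    // 4. working variances: univariate inverse-Wishart (V, nu) updates
    if (qs) {
      double shape = 0.5 * (nu_s + S);
      double rate = 0.5 * (nu_s * V_s + arma::dot(eta_s, eta_s));
      s2es = rate / R::rgamma(shape, 1.0);
    }
    if (qp) {
      double shape = 0.5 * (nu_p + S);
      double rate = 0.5 * (nu_p * V_p +
                           arma::as_scalar(eta_p.t() * Ainv * eta_p));
      s2ep = rate / R::rgamma(shape, 1.0);
    }

    // 5. retain
    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      beta_draws.row(kept) = beta.t();
      if (qs) { var_draws(kept, 0) = alpha_s * alpha_s * s2es;
                us_mean += alpha_s * eta_s; }
      if (qp) { var_draws(kept, 1) = alpha_p * alpha_p * s2ep;
                up_mean += alpha_p * eta_p; }
      ++kept;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (kept > 0) { us_mean /= kept; up_mean /= kept; }

  return List::create(_["beta"] = beta_draws,
                      _["sigma2"] = var_draws,
                      _["u_species"] = us_mean,
                      _["u_phylo"] = up_mean,
                      _["n_kept"] = kept,
                      _["diverged"] = diverged);
}
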