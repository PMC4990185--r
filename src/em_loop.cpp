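// EM iteration engine for the multivariate linear mixed model with
// homoscedastic per-dimension residuals. Works entirely on per-group
// sufficient statistics (cross-products), so one iteration costs
// O(n * q^3) with q the total number of random effects per group.
//
// Posterior moments use the precision form
//   W_i = (Gbar^{-1} + Z_i' Sigma^{-1} Z_i)^{-1},  m_i = W_i Z_i' Sigma^{-1} r_i
// and the observed-data log-likelihood uses the matched determinant and
// quadratic-form identities, so the stacked N_i x N_i covariance is never
// formed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct DimStats {
  arma::cube XtX, ZtX, ZtZ;
  arma::mat Xty, Zty;
  arma::vec yty;
  arma::ivec Ni;
};

// spectral floor applied only if a Cholesky of the covariance iterate fails
static arma::mat psd_floor(const arma::mat& G) {
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, arma::symmatu(G));
  double fl = std::max(1e-10 * std::max(ev.max(), 0.0), 1e-300);
  ev.transform([fl](double v) { return v < fl ? fl : v; });
  return V * arma::diagmat(ev) * V.t();
}

struct PassResult {
  double ll;
  arma::mat postM;   // q x n posterior means
  arma::cube Wcube;  // q x q x n posterior covariances
  arma::mat Gacc;    // sum_i (W_i + m_i m_i')
  std::vector<arma::vec> bacc;  // sum_i X_ki' Z_ki m_ki per dimension
};

static void estep_pass(const std::vector<DimStats>& st,
                       const std::vector<arma::uword>& off,
                       const arma::ivec& q,
                       const std::vector<arma::vec>& beta,
                       arma::mat G, const arma::vec& sig2,
                       int n, PassResult& out) {
  int m = (int)st.size();
  arma::uword qtot = G.n_rows;
  arma::mat cG;
  if (!arma::chol(cG, G)) {
    G = psd_floor(G);
    if (!arma::chol(cG, G)) stop("random-effects covariance irreparably singular");
  }
  double logdetG = 2.0 * arma::accu(arma::log(cG.diag()));
  arma::mat cGi = arma::inv(arma::trimatu(cG));
  arma::mat Ginv = cGi * cGi.t();

  out.ll = 0.0;
  out.postM.zeros(qtot, n);
  out.Wcube.zeros(qtot, qtot, n);
  out.Gacc.zeros(qtot, qtot);
  out.bacc.resize(m);
  for (int k = 0; k < m; ++k) out.bacc[k].zeros(st[k].Xty.n_rows);

  for (int i = 0; i < n; ++i) {
    arma::mat M = Ginv;
    arma::vec u(qtot, arma::fill::zeros);
    double quad = 0.0, nlog = 0.0;
    double Ntot = 0.0;
    for (int k = 0; k < m; ++k) {
      int Nki = st[k].Ni(i);
      if (Nki == 0) continue;
      arma::span sp(off[k], off[k] + q(k) - 1);
      M.submat(sp, sp) += st[k].ZtZ.slice(i) / sig2(k);
      arma::vec zr = st[k].Zty.col(i) - st[k].ZtX.slice(i) * beta[k];
      u.subvec(sp) += zr / sig2(k);
      double rr = st[k].yty(i) - 2.0 * arma::dot(beta[k], st[k].Xty.col(i)) +
        arma::as_scalar(beta[k].t() * st[k].XtX.slice(i) * beta[k]);
      quad += rr / sig2(k);
      nlog += Nki * std::log(sig2(k));
      Ntot += Nki;
    }
    arma::mat cM;
    if (!arma::chol(cM, M)) stop("singular posterior precision in a group");
    double logdetM = 2.0 * arma::accu(arma::log(cM.diag()));
    arma::mat cMi = arma::inv(arma::trimatu(cM));
    arma::mat W = cMi * cMi.t();
    arma::vec mv = W * u;
    out.ll += -0.5 * (Ntot * LOG2PI + logdetG + logdetM + nlog +
                      quad - arma::dot(u, mv));
    out.postM.col(i) = mv;
    out.Wcube.slice(i) = W;
    out.Gacc += W + mv * mv.t();
    for (int k = 0; k < m; ++k) {
      if (st[k].Ni(i) == 0) continue;
      arma::span sp(off[k], off[k] + q(k) - 1);
      out.bacc[k] += st[k].ZtX.slice(i).t() * mv.subvec(sp);
    }
  }
}

static arma::vec pack_params(const std::vector<arma::vec>& beta,
                             const arma::mat& G, const arma::vec& sig2) {
  std::vector<double> v;
  for (const auto& b : beta)
    for (arma::uword j = 0; j < b.n_elem; ++j) v.push_back(b(j));
  for (arma::uword c = 0; c < G.n_cols; ++c)
    for (arma::uword r = c; r < G.n_rows; ++r) v.push_back(G(r, c));
  for (arma::uword k = 0; k < sig2.n_elem; ++k) v.push_back(sig2(k));
  return arma::vec(v);
}

// [[Rcpp::export]]
List em_loop_cpp(List per_dim, IntegerVector p, IntegerVector q_,
                 NumericVector Nk, List beta_init, arma::mat G,
                 arma::vec sig2, double tol, int max_iter,
                 double denom_floor) {
  int m = per_dim.size();
  arma::ivec q(m);
  for (int k = 0; k < m; ++k) q(k) = q_[k];
  std::vector<DimStats> st(m);
  int n = 0;
  for (int k = 0; k < m; ++k) {
    List dk = per_dim[k];
    st[k].XtX = as<arma::cube>(dk["XtX"]);
    st[k].ZtX = as<arma::cube>(dk["ZtX"]);
    st[k].ZtZ = as<arma::cube>(dk["ZtZ"]);
    st[k].Xty = as<arma::mat>(dk["Xty"]);
    st[k].Zty = as<arma::mat>(dk["Zty"]);
    st[k].yty = as<arma::vec>(dk["yty"]);
    st[k].Ni = as<arma::ivec>(dk["Ni"]);
    n = st[k].Ni.n_elem;
  }
  std::vector<arma::uword> off(m);
  arma::uword acc = 0;
  for (int k = 0; k < m; ++k) { off[k] = acc; acc += q(k); }

  std::vector<arma::vec> beta(m);
  std::vector<arma::mat> XtX_sum(m);
  std::vector<arma::vec> Xty_sum(m);
  for (int k = 0; k < m; ++k) {
    beta[k] = as<arma::vec>(beta_init[k]);
    XtX_sum[k] = arma::sum(st[k].XtX, 2);
    Xty_sum[k] = arma::sum(st[k].Xty, 1);
  }

  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false;
  int iterations = 0;
  int decrease_iter = NA_INTEGER;
  arma::vec old_vec = pack_params(beta, G, sig2);
  PassResult pr;

  for (int iter = 1; iter <= max_iter; ++iter) {
    estep_pass(st, off, q, beta, G, sig2, n, pr);
    if (!trace.empty()) {
      double drop = (trace.back() - pr.ll) / (std::fabs(trace.back()) + 1.0);
      if (drop > 1e-8 && decrease_iter == NA_INTEGER) decrease_iter = iter - 1;
    }
    trace.push_back(pr.ll);

    // M-step
    std::vector<arma::vec> beta_new(m);
    for (int k = 0; k < m; ++k) {
      arma::vec rhs = Xty_sum[k] - pr.bacc[k];
      if (!arma::solve(beta_new[k], XtX_sum[k], rhs,
                       arma::solve_opts::likely_sympd))
        stop("singular fixed-effect design");
    }
    arma::vec sig2_new(m);
    for (int k = 0; k < m; ++k) {
      double a = 0.0;
      arma::span sp(off[k], off[k] + q(k) - 1);
      for (int i = 0; i < n; ++i) {
        int Nki = st[k].Ni(i);
        if (Nki == 0) continue;
        arma::vec mk = pr.postM(sp, arma::span(i, i));
        double resid2 = st[k].yty(i)
          - 2.0 * arma::dot(beta_new[k], st[k].Xty.col(i))
          + arma::as_scalar(beta_new[k].t() * st[k].XtX.slice(i) * beta_new[k])
          - 2.0 * arma::dot(mk, st[k].Zty.col(i))
          + 2.0 * arma::as_scalar(mk.t() * st[k].ZtX.slice(i) * beta_new[k])
          + arma::as_scalar(mk.t() * st[k].ZtZ.slice(i) * mk);
        double tr = arma::accu(st[k].ZtZ.slice(i) %
                               pr.Wcube.slice(i).submat(sp, sp));
        a += tr + resid2;
      }
      sig2_new(k) = std::max(a / Nk[k], 1e-12);
    }
    arma::mat G_new = arma::symmatl(pr.Gacc / (double)n);

    beta = beta_new;
    sig2 = sig2_new;
    G = G_new;
    iterations = iter;

    arma::vec new_vec = pack_params(beta, G, sig2);
    double rel = 0.0;
    for (arma::uword j = 0; j < new_vec.n_elem; ++j) {
      double r = std::fabs(new_vec(j) - old_vec(j)) /
        (std::fabs(new_vec(j)) + denom_floor);
      if (r > rel) rel = r;
    }
    old_vec = new_vec;
    if (rel < tol) { converged = true; break; }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  // final evaluation and posterior at the converged parameters
  estep_pass(st, off, q, beta, G, sig2, n, pr);
  if (!trace.empty()) {
    double drop = (trace.back() - pr.ll) / (std::fabs(trace.back()) + 1.0);
    if (drop > 1e-8 && decrease_iter == NA_INTEGER) decrease_iter = iterations;
  }
  trace.push_back(pr.ll);

  List betas_out(m);
  for (int k = 0; k < m; ++k) betas_out[k] = NumericVector(beta[k].begin(), beta[k].end());
  arma::mat post_cov_mat(G.n_rows * G.n_rows, n);
  for (int i = 0; i < n; ++i)
    post_cov_mat.col(i) = arma::vectorise(pr.Wcube.slice(i));

  return List::create(
    _["betas"] = betas_out,
    _["gamma_bar"] = G,
    _["sigma2"] = NumericVector(sig2.begin(), sig2.end()),
    _["loglik"] = pr.ll,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["iterations"] = iterations,
    _["converged"] = converged,
    _["post_mean_mat"] = pr.postM,
    _["post_cov_mat"] = post_cov_mat,
    _["decrease_iter"] = decrease_iter);
}
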