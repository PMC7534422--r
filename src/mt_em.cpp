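// EM-REML for the multi-trait GBLUP model in the eigenbasis of the
// relationship matrix.
//
// Model (after rotation by the eigenvectors of K, rows independent):
//   y_i ~ N(B x_i, lambda_i * G + R),  i = 1..m
// optionally augmented by an independent Wishart part on R carrying the
// within-plant contrasts of fruit-level records: nu degrees of freedom with
// accumulated cross-products SSW. G may be constrained diagonal.
//
// Returns REML estimates of G, R, the fixed-effect matrix B (T x p), the
// per-row prediction kernels S_i = G V_i^-1 r_i used for GBLUP prediction,
// and the restricted log-likelihood trace (up to an additive constant).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat bend_psd_cpp(const mat& M, double eps = 1e-6) {
  mat S = symmatu((M + M.t()) / 2.0);
  vec ev; mat V;
  eig_sym(ev, V, S);
  double fl = eps * std::max(trace(S), 1e-300);
  if (ev.min() >= fl) return S;
  ev = clamp(ev, fl, datum::inf);
  return symmatu(V * diagmat(ev) * V.t());
}

struct EvalOut {
  double ll;
  mat Gacc, Racc, B, S;
};

// one E-step / likelihood evaluation at (G, R)
static EvalOut mt_eval(const mat& Y, const mat& X, const vec& lambda,
                       const mat& SSW, double nu, const mat& G, const mat& R) {
  const uword m = Y.n_rows, T = Y.n_cols, p = X.n_cols;
  cube Vinv(T, T, m);
  mat A(p * T, p * T, fill::zeros);
  vec rvec(p * T, fill::zeros);
  double ll = 0.0;
  for (uword i = 0; i < m; ++i) {
    mat V = lambda(i) * G + R;
    mat Vi;
    if (!inv_sympd(Vi, V)) Vi = pinv(symmatu(V));
    Vinv.slice(i) = Vi;
    double sign, ldV;
    log_det(ldV, sign, symmatu(V));
    ll += ldV;
    vec yi = Y.row(i).t();
    vec xi = X.row(i).t();
    for (uword a = 0; a < p; ++a) {
      for (uword b = 0; b < p; ++b)
        A.submat(a * T, b * T, (a + 1) * T - 1, (b + 1) * T - 1) += xi(a) * xi(b) * Vi;
      rvec.subvec(a * T, (a + 1) * T - 1) += xi(a) * (Vi * yi);
    }
  }
  mat Ainv = inv_sympd(symmatu(A));
  vec bvec = Ainv * rvec;
  mat B(bvec.memptr(), T, p);   // column a holds coefficients of covariate a
  double sign, ldA;
  log_det(ldA, sign, symmatu(A));
  ll += ldA;

  mat Rinv;
  if (!inv_sympd(Rinv, R)) Rinv = pinv(symmatu(R));
  if (nu > 0) {
    double ldR; log_det(ldR, sign, symmatu(R));
    ll += nu * ldR + trace(Rinv * SSW);
  }

  mat Gacc(T, T, fill::zeros), Racc(T, T, fill::zeros), S(m, T, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    vec xi = X.row(i).t();
    vec ri = Y.row(i).t() - B * xi;
    const mat& Vi = Vinv.slice(i);
    vec si = Vi * ri;
    ll += dot(ri, si);
    // H_i = Var of the estimated mean at row i
    mat H(T, T, fill::zeros);
    for (uword a = 0; a < p; ++a)
      for (uword b = 0; b < p; ++b)
        H += xi(a) * xi(b) * Ainv.submat(a * T, b * T, (a + 1) * T - 1, (b + 1) * T - 1);
    mat GVi = G * Vi;
    vec ui = lambda(i) * (G * si);
    vec ei = ri - ui;
    // E[u u'/lambda | y], stable as lambda -> 0
    Gacc += lambda(i) * (GVi * (ri * ri.t()) * GVi.t())
          + G - lambda(i) * (GVi * G)
          + lambda(i) * (GVi * H * GVi.t());
    mat RVi = R * Vi;
    Racc += ei * ei.t() + R - RVi * R + RVi * H * RVi.t();
    S.row(i) = (G * si).t();
  }
  EvalOut out;
  out.ll = -0.5 * ll;
  out.Gacc = symmatu((Gacc + Gacc.t()) / 2.0);
  out.Racc = symmatu((Racc + Racc.t()) / 2.0);
  out.B = B;
  out.S = S;
  return out;
}

// [[Rcpp::export(name = ".mt_em_core")]]
Rcpp::List mt_em_core(const arma::mat& Y, const arma::mat& X,
                      const arma::vec& lambda, const arma::mat& SSW,
                      double nu, bool diagG, double tol, int maxit,
                      const arma::mat& G0, const arma::mat& R0) {
  const uword m = Y.n_rows;
  const uword T = Y.n_cols;
  mat G = bend_psd_cpp(G0), R = bend_psd_cpp(R0);
  std::vector<double> trace_ll;
  double ll_prev = -datum::inf;
  bool converged = false;
  int it = 0;
  EvalOut ev;
  // Aitken extrapolation history over the stacked (G, R) elements: EM has a
  // linear rate, so geometric extrapolation accelerates the tail; candidates
  // are kept only when they improve the restricted likelihood.
  std::vector<vec> hist;
  auto pack = [&](const mat& Gm, const mat& Rm) -> vec {
    vec out = join_cols(vectorise(Gm), vectorise(Rm));
    return out;
  };
  for (it = 1; it <= maxit; ++it) {
    ev = mt_eval(Y, X, lambda, SSW, nu, G, R);
    trace_ll.push_back(ev.ll);
    if (std::abs(ev.ll - ll_prev) < tol) { converged = true; break; }
    ll_prev = ev.ll;
    mat Gnew = ev.Gacc / double(m);
    mat Rnew = (SSW + ev.Racc) / (nu + double(m));
    if (diagG) Gnew = diagmat(Gnew.diag());
    G = bend_psd_cpp(Gnew);
    R = bend_psd_cpp(Rnew);
    hist.push_back(pack(G, R));
    if (hist.size() > 3) hist.erase(hist.begin());
    if (it % 5 == 0 && hist.size() == 3) {
      vec d1 = hist[1] - hist[0], d2 = hist[2] - hist[1];
      vec cand = hist[2];
      for (uword k = 0; k < cand.n_elem; ++k) {
        double r = (std::abs(d1(k)) > 1e-14) ? d2(k) / d1(k) : 0.0;
        r = std::min(std::max(r, 0.0), 0.995);
        cand(k) += r / (1.0 - r) * d2(k);
      }
      mat Gc(cand.memptr(), T, T);
      mat Rc(cand.memptr() + T * T, T, T);
      if (diagG) Gc = diagmat(Gc.diag());
      Gc = bend_psd_cpp(Gc);
      Rc = bend_psd_cpp(Rc);
      EvalOut evc = mt_eval(Y, X, lambda, SSW, nu, Gc, Rc);
      if (std::isfinite(evc.ll) && evc.ll >= ev.ll) {
        G = Gc; R = Rc;
        hist.clear();
      }
    }
  }
  // final evaluation so the reported likelihood and kernels match (G, R)
  ev = mt_eval(Y, X, lambda, SSW, nu, G, R);
  return Rcpp::List::create(
    Rcpp::Named("G") = G, Rcpp::Named("R") = R, Rcpp::Named("B") = ev.B,
    Rcpp::Named("S") = ev.S, Rcpp::Named("loglik") = ev.ll,
    Rcpp::Named("loglik_trace") = trace_ll,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = std::min(it, maxit));
}
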