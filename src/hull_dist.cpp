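// Distance from a query point to the convex hull of a vertex set.
//
// Solves  min || V' lambda - q ||  s.t.  lambda >= 0, sum(lambda) = 1
// by Lawson-Hanson non-negative least squares on the augmented system
// [ V' ; M 1' ] lambda ~ [ q ; M ].  For q inside conv(V) the augmented
// residual is exactly attainable at 0, so the returned distance is at
// machine precision; for q outside, lambda is renormalized to the simplex
// and the true Euclidean distance to the induced combination is returned
// (an upper bound tight to O(1/M^2)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec nnls_lh(const mat& A, const vec& b, int itmax) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);
  double tol = 10.0 * datum::eps * norm(A, 2) * (double)std::max(A.n_rows, n);
  int iter = 0;

  while (true) {
    // pick most violated zero-set coefficient
    int t = -1; double wmax = tol;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    if (t < 0) break;
    passive[t] = true;

    while (true) {
      uvec P(n); uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec zP;
      bool ok = solve(zP, A.cols(P), b, solve_opts::fast + solve_opts::no_approx);
      if (!ok) zP = pinv(A.cols(P)) * b;
      if (zP.min() > tol) {
        x.zeros();
        for (uword j = 0; j < np; ++j) x(P(j)) = zP(j);
        break;
      }
      if (++iter > itmax) {  // stalled: accept clipped solution
        x.zeros();
        for (uword j = 0; j < np; ++j) x(P(j)) = std::max(zP(j), 0.0);
        return x;
      }
      // step back along the segment to the feasibility boundary
      double alpha = datum::inf;
      for (uword j = 0; j < np; ++j) {
        if (zP(j) <= tol) {
          double xi = x(P(j));
          double a = xi / (xi - zP(j));
          if (a < alpha) alpha = a;
        }
      }
      for (uword j = 0; j < np; ++j) {
        x(P(j)) += alpha * (zP(j) - x(P(j)));
        if (x(P(j)) < tol) { x(P(j)) = 0.0; passive[P(j)] = false; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// V: m x d matrix of hull vertex coordinates (rows); q: length-d query.
// Returns list(dist, lambda): Euclidean distance from q to conv(rows of V)
// and the simplex weights attaining it.
// [[Rcpp::export]]
Rcpp::List hull_dist_cpp(const arma::mat& V, const arma::vec& q) {
  const uword m = V.n_rows, d = V.n_cols;
  if (q.n_elem != d) Rcpp::stop("dimension mismatch between hull and query");
  if (m == 1) {
    double dd = norm(V.row(0).t() - q, 2);
    return Rcpp::List::create(Rcpp::Named("dist") = dd,
                              Rcpp::Named("lambda") = vec(1, fill::ones));
  }
  // center and scale for conditioning
  rowvec ctr = mean(V, 0);
  mat Vc = V.each_row() - ctr;
  vec qc = q - ctr.t();
  double s = std::max(abs(Vc).max(), abs(qc).max());
  if (s <= 0) s = 1.0;
  Vc /= s; qc /= s;

  const double M = 16.0;  // sum-constraint penalty weight after scaling
  mat A(d + 1, m);
  A.rows(0, d - 1) = Vc.t();
  A.row(d).fill(M);
  vec b(d + 1);
  b.subvec(0, d - 1) = qc;
  b(d) = M;

  vec lam = nnls_lh(A, b, 30 * (int)m + 100);
  double ls = accu(lam);
  if (ls <= 0) { lam.fill(1.0 / m); ls = 1.0; }
  lam /= ls;
  vec r = Vc.t() * lam - qc;
  return Rcpp::List::create(Rcpp::Named("dist") = s * norm(r, 2),
                            Rcpp::Named("lambda") = lam);
}

// Batch: distances from each row of Q to conv(rows of V).
// [[Rcpp::export]]
arma::vec hull_dist_many_cpp(const arma::mat& V, const arma::mat& Q) {
  vec out(Q.n_rows);
  for (uword i = 0; i < Q.n_rows; ++i) {
    Rcpp::List r = hull_dist_cpp(V, Q.row(i).t());
    out(i) = Rcpp::as<double>(r["dist"]);
  }
  return out;
}

// Hull vertex identification: row i of P is a vertex of conv(P) iff its
// distance to the hull of the remaining rows exceeds tol.
// [[Rcpp::export]]
arma::uvec hull_vertices_cpp(const arma::mat& P, const double tol) {
  const uword m = P.n_rows;
  uvec keep(m, fill::zeros);
  if (m <= 2) { keep.fill(1); return keep; }
  for (uword i = 0; i < m; ++i) {
    mat rest(m - 1, P.n_cols);
    uword r = 0;
    for (uword j = 0; j < m; ++j) if (j != i) rest.row(r++) = P.row(j);
    Rcpp::List res = hull_dist_cpp(rest, P.row(i).t());
    if (Rcpp::as<double>(res["dist"]) > tol) keep(i) = 1;
  }
  return keep;
}
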