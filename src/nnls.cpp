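// Batched non-negative least squares on a precomputed Gram matrix.
//
// Each ALS half-iteration solves, for every pixel row (or channel
// column) independently,
//     min_x || A x - b ||_2   s.t.  x >= 0,
// where A is the fixed factor. Only G = A'A (k x k, k small) and
// f = A'b vary per problem, so everything runs on G and f.
//
// The batched driver uses block principal pivoting (Van Benthem &
// Keenan's fast combinatorial NNLS): all right-hand sides iterate their
// passive/active partitions in lockstep, and rows sharing a passive-set
// pattern are solved with a single k x k factorization. Rows that fail
// to settle (near-singular subproblems) fall back to a per-row
// Lawson-Hanson active-set solve, so the result is always the exact
// constrained minimiser, never a clipped unconstrained solution.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// solve G_FF z = f_F for one passive set; pinv fallback for rank-deficiency
static bool solve_passive(const mat& G, const uvec& F, const mat& Fsub,
                          mat& Z) {
  mat GFF = G.submat(F, F);
  if (solve(Z, GFF, Fsub, solve_opts::likely_sympd + solve_opts::no_approx))
    return true;
  Z = pinv(GFF) * Fsub;
  return true;
}

// classic Lawson-Hanson active set on the Gram system (fallback path)
static vec nnls_lh(const mat& G, const vec& f, double tol) {
  const uword k = G.n_rows;
  vec x(k, fill::zeros);
  uvec passive(k, fill::zeros);
  for (uword outer = 0; outer < 5 * k + 50; ++outer) {
    vec w = f - G * x;
    double wmax = -datum::inf; sword jmax = -1;
    for (uword j = 0; j < k; ++j)
      if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (jmax < 0 || wmax <= tol) break;
    passive(jmax) = 1;
    for (uword inner = 0; inner < 5 * k + 50; ++inner) {
      uvec F = find(passive);
      mat Z;
      solve_passive(G, F, f.elem(F), Z);
      vec z = Z.col(0);
      if (z.min() > 0) {
        x.zeros();
        x.elem(F) = z;
        break;
      }
      double alpha = datum::inf;
      for (uword i = 0; i < F.n_elem; ++i)
        if (z(i) <= 0) {
          double d = x(F(i)) - z(i);
          if (d > 0) alpha = std::min(alpha, x(F(i)) / d);
        }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword i = 0; i < F.n_elem; ++i)
        x(F(i)) += alpha * (z(i) - x(F(i)));
      bool dropped = false;
      for (uword i = 0; i < F.n_elem; ++i)
        if (x(F(i)) <= tol) { x(F(i)) = 0; passive(F(i)) = 0; dropped = true; }
      if (!dropped) {
        x.zeros();
        z.transform([](double v) { return v > 0 ? v : 0.0; });
        x.elem(F) = z;
        break;
      }
      if (!any(passive)) break;
    }
  }
  x.transform([](double v) { return v > 0 ? v : 0.0; });
  return x;
}

//' @title Batched non-negative least squares on a Gram matrix
//' @description Solves \code{min_x ||A x - b||} subject to \code{x >= 0}
//'   for many right-hand sides sharing one Gram matrix \code{G = A'A};
//'   row \code{i} of \code{FtB} holds \code{A' b_i}.
//' @param G k x k symmetric positive semi-definite Gram matrix.
//' @param FtB m x k matrix; row i is the projected right-hand side.
//' @param tol KKT / pivot tolerance (scaled by \code{max(diag(G))}).
//' @return m x k matrix of non-negative solutions, one row per problem.
//' @keywords internal
// [[Rcpp::export]]
arma::mat nnls_gram(const arma::mat& G, const arma::mat& FtB,
                    double tol = 1e-12) {
  if (G.n_rows != G.n_cols) Rcpp::stop("G must be square");
  if (FtB.n_cols != G.n_rows) Rcpp::stop("ncol(FtB) must equal nrow(G)");
  const uword m = FtB.n_rows, k = G.n_rows;
  double g = G.diag().max();
  const double eps = tol * (g > 0 ? g : 1.0);

  mat X(m, k, fill::zeros);
  if (k > 62) {                       // bitmask grouping capped; LH per row
    for (uword i = 0; i < m; ++i) X.row(i) = nnls_lh(G, FtB.row(i).t(), eps).t();
    return X;
  }

  mat Y(m, k, fill::zeros);           // dual: y = G x - f on active set
  std::vector<uint64_t> mask(m, (k == 62) ? ~uint64_t(0) >> 2
                                          : (uint64_t(1) << k) - 1);
  std::vector<int> backup(m, 3), ninf(m, int(k) + 1);
  std::vector<bool> done(m, false);
  std::vector<uword> pending(m);
  for (uword i = 0; i < m; ++i) pending[i] = i;

  const uword max_pivot = 10 * k + 30;
  for (uword it = 0; it < max_pivot && !pending.empty(); ++it) {
    // group pending rows by passive-set pattern and solve per pattern
    std::unordered_map<uint64_t, std::vector<uword>> groups;
    for (uword i : pending) groups[mask[i]].push_back(i);
    for (auto& kv : groups) {
      uint64_t pat = kv.first;
      std::vector<uword>& rows = kv.second;
      uvec idx(rows.size());
      for (size_t r = 0; r < rows.size(); ++r) idx(r) = rows[r];
      uvec F(k); uword nf = 0;
      for (uword j = 0; j < k; ++j) if (pat & (uint64_t(1) << j)) F(nf++) = j;
      F.resize(nf);
      mat Frhs = FtB.submat(idx, F).t();       // nf x nrows
      if (nf == 0) {
        for (size_t r = 0; r < rows.size(); ++r) {
          X.row(rows[r]).zeros();
          Y.row(rows[r]) = -FtB.row(rows[r]); // y = -f when x = 0
        }
        continue;
      }
      mat Z;
      solve_passive(G, F, Frhs, Z);            // nf x nrows
      // scatter solution and duals
      uvec Gset(k); uword ng = 0;
      for (uword j = 0; j < k; ++j) if (!(pat & (uint64_t(1) << j))) Gset(ng++) = j;
      Gset.resize(ng);
      mat Yg;
      if (ng > 0) Yg = G.submat(Gset, F) * Z - FtB.submat(idx, Gset).t();
      for (size_t r = 0; r < rows.size(); ++r) {
        uword i = rows[r];
        X.row(i).zeros();
        for (uword q = 0; q < nf; ++q) X(i, F(q)) = Z(q, r);
        Y.row(i).zeros();
        for (uword q = 0; q < ng; ++q) Y(i, Gset(q)) = Yg(q, r);
      }
    }
    // pivot rule per row
    std::vector<uword> still;
    for (uword i : pending) {
      uint64_t viol = 0;
      int nv = 0;
      sword last = -1;
      for (uword j = 0; j < k; ++j) {
        bool inF = mask[i] & (uint64_t(1) << j);
        double bad = inF ? X(i, j) : Y(i, j);
        if (bad < -eps) { viol |= uint64_t(1) << j; ++nv; last = j; }
      }
      if (nv == 0) { done[i] = true; continue; }
      if (nv < ninf[i]) { ninf[i] = nv; backup[i] = 3; mask[i] ^= viol; }
      else if (backup[i] > 0) { --backup[i]; mask[i] ^= viol; }
      else { mask[i] ^= (uint64_t(1) << last); } // Murty's single exchange
      still.push_back(i);
    }
    pending.swap(still);
  }
  // rows that cycled out of the pivot budget: exact LH fallback
  for (uword i : pending) X.row(i) = nnls_lh(G, FtB.row(i).t(), eps).t();

  X.transform([](double v) { return v > 0 ? v : 0.0; });
  return X;
}

//' @title Residual sum of squares of a bilinear model
//' @description Computes \code{||D - C S||_F^2} blockwise without
//'   materialising a full residual matrix.
//' @param D pixels x channels data matrix.
//' @param C pixels x k scores.
//' @param S k x channels loadings.
//' @return the squared Frobenius norm of the residual.
//' @keywords internal
// [[Rcpp::export]]
double resid_ss(const arma::mat& D, const arma::mat& C, const arma::mat& S) {
  if (D.n_rows != C.n_rows || D.n_cols != S.n_cols || C.n_cols != S.n_rows)
    Rcpp::stop("non-conformable factors");
  const uword block = 4096;
  double acc = 0.0;
  for (uword r0 = 0; r0 < D.n_rows; r0 += block) {
    uword r1 = std::min(D.n_rows - 1, r0 + block - 1);
    acc += accu(square(D.rows(r0, r1) - C.rows(r0, r1) * S));
  }
  return acc;
}
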