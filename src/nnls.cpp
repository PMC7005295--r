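#include <RcppArmadillo.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fast separability pre-check: dual coordinate descent on the L2-loss SVM
// (large C approximates the hard margin).  Returns 1 only when a strict
// separating certificate w is found (min_i z_i . w > margin_tol ||w||);
// 0 means "undecided" and the caller falls back to the exact hull test.
// Z: rows are label-signed, unit-norm samples.
// [[Rcpp::export(name = ".sep_precheck_cpp")]]
int sep_precheck_cpp(const arma::mat& Z, int max_epochs = 60,
                     double margin_tol = 1e-6) {
  const uword m = Z.n_rows, n = Z.n_cols;
  const double C2 = 1.0 / (2.0 * 1e6);      // 1/(2C)
  vec alpha(m, fill::zeros), w(n, fill::zeros);
  for (int ep = 0; ep < max_epochs; ++ep) {
    for (uword i = 0; i < m; ++i) {
      double g = dot(Z.row(i), w) - 1.0 + alpha(i) * C2;
      double d = -g / (1.0 + C2);
      double a_new = std::max(0.0, alpha(i) + d);
      double da = a_new - alpha(i);
      if (da != 0.0) { w += da * Z.row(i).t(); alpha(i) = a_new; }
    }
    double nw = norm(w, 2);
    if (nw > 0) {
      double mn = datum::inf;
      for (uword i = 0; i < m; ++i)
        mn = std::min(mn, dot(Z.row(i), w));
      if (mn > margin_tol * nw) return 1;
    }
  }
  return 0;
}

// Lawson-Hanson active-set NNLS: min_{x >= 0} ||A x - b||^2.
//
// The Cholesky factor R of A_P' A_P (P = passive set) lives in a
// preallocated cap x cap buffer and is grown by one column per entering
// variable (O(k^2)) and shrunk by Givens re-triangularization per leaving
// variable (O(k^2)); no per-iteration allocations.  Block pivoting
// (FNNLS-style) adds up to `block` violating columns per exact-gradient
// refresh.  Exactness is unaffected: termination is always decided on a
// freshly computed gradient.
//
// Two optional early exits serve the separability decision (columns of A
// are label-signed unit samples plus a constant row, b = (0,...,0,1)):
//  * stop_resid > 0: LH residual norms decrease monotonically, so once
//    ||r|| < stop_resid the final hull distance is below the decision
//    threshold (status 2, "origin inside the hull").
//  * certificate: with w = A_{1:m-1}' x the margin min_i z_i . w equals
//    -max_i grad_i - (sum x - 1), free at each refresh; a strictly
//    positive value proves separability (status 1).
struct NNLSResult {
  vec x;
  vec resid;      // A x - b
  double rnorm;
  int iters;
  bool converged;
  int status;     // 0 = KKT optimum, 1 = certificate exit, 2 = resid exit
};

class LHFactor {
public:
  LHFactor(const mat& A, uword cap)
      : A_(A), cap_(cap), k_(0), R_(cap, cap, fill::zeros),
        AP_(A.n_rows, cap, fill::zeros) {}

  uword size() const { return k_; }

  // returns false when the column is numerically dependent
  bool add(uword j) {
    const vec a = A_.col(j);
    double aa = dot(a, a);
    if (k_ == 0) {
      if (aa <= 0) return false;
      R_(0, 0) = std::sqrt(aa);
    } else {
      // v = AP' a ; r = solve(R', v) ; diag = sqrt(a'a - r'r)
      vec v(k_);
      for (uword i = 0; i < k_; ++i) v(i) = dot(AP_.col(i), a);
      forward_solve(v);                 // v <- R'^{-1} v
      double d = aa - dot(v, v);
      if (d <= 1e-10 * aa) return false;
      for (uword i = 0; i < k_; ++i) R_(i, k_) = v(i);
      R_(k_, k_) = std::sqrt(d);
    }
    AP_.col(k_) = a;
    ++k_;
    return true;
  }

  // Givens downdate after deleting passive position idx
  void remove(uword idx) {
    for (uword c = idx; c + 1 < k_; ++c) {
      // shift column c+1 of R into c (rows 0..c+1), and AP likewise
      for (uword rr = 0; rr <= c + 1; ++rr) R_(rr, c) = R_(rr, c + 1);
      AP_.col(c) = AP_.col(c + 1);
      double a1 = R_(c, c), b1 = R_(c + 1, c);
      if (b1 != 0.0) {
        double h = std::hypot(a1, b1), cs = a1 / h, sn = b1 / h;
        R_(c, c) = h; R_(c + 1, c) = 0.0;
        for (uword cc = c + 1; cc + 1 < k_; ++cc) {
          double t1 = R_(c, cc + 1), t2 = R_(c + 1, cc + 1);
          R_(c, cc + 1) = cs * t1 + sn * t2;
          R_(c + 1, cc + 1) = -sn * t1 + cs * t2;
        }
      }
    }
    --k_;
    for (uword rr = 0; rr <= k_; ++rr) R_(rr, k_) = 0.0;
    AP_.col(k_).zeros();
  }

  // z = (A_P' A_P)^{-1} rhs via the triangular factor
  void solve_normal(vec& z) const {
    forward_solve(z);
    backward_solve(z);
  }

  // y = AP * xP  (O(m k))
  vec ap_times(const vec& xP) const {
    vec y(A_.n_rows, fill::zeros);
    for (uword i = 0; i < k_; ++i) y += AP_.col(i) * xP(i);
    return y;
  }

private:
  void forward_solve(vec& v) const {     // v <- R'^{-1} v  (lower tri R')
    int k = (int)v.n_elem, lda = (int)cap_, inc = 1;
    if (k == 0) return;
    F77_CALL(dtrsv)("U", "T", "N", &k, R_.memptr(), &lda, v.memptr(),
                    &inc FCONE FCONE FCONE);
  }
  void backward_solve(vec& v) const {    // v <- R^{-1} v   (upper tri R)
    int k = (int)v.n_elem, lda = (int)cap_, inc = 1;
    if (k == 0) return;
    F77_CALL(dtrsv)("U", "N", "N", &k, R_.memptr(), &lda, v.memptr(),
                    &inc FCONE FCONE FCONE);
  }

  const mat& A_;
  uword cap_, k_;
  mat R_, AP_;
};

static NNLSResult nnls_core(const mat& A, const vec& b, double tol,
                            int max_iter, double stop_resid,
                            bool certificate) {
  const uword n = A.n_cols;
  const uword m = A.n_rows;
  NNLSResult res;
  res.x = zeros<vec>(n);
  res.converged = true;
  res.status = 0;
  res.iters = 0;

  if (max_iter <= 0) max_iter = 10 * static_cast<int>(std::min(n, 4 * m)) +
    200;

  vec Atb = A.t() * b;
  vec w = Atb;                      // gradient of -f: A'(b - A x)
  if (tol <= 0.0) {
    double scale = norm(b, 2) * (m > 0 ? norm(A, "fro") /
                                 std::sqrt((double)n) : 1.0);
    tol = 1e-12 * std::max(1.0, scale);
  }

  std::vector<uword> P;
  std::vector<char> inP(n, 0);
  LHFactor F(A, std::min(n, m) + 2);
  vec x = res.x;

  const uword block = 32;
  int it = 0;
  bool outer_done = false;
  while (!outer_done) {
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < n; ++j)
      if (!inP[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (certificate) {
      double margin = -wmax - (accu(x) - 1.0);
      if (jmax >= 0 && margin > 1e-10) { res.status = 1; break; }
    }
    if (jmax < 0 || wmax <= tol) break;   // KKT satisfied

    uvec ord = sort_index(w, "descend");
    std::vector<uword> cand;
    for (uword t = 0; t < ord.n_elem && cand.size() < block; ++t) {
      uword j = ord(t);
      if (!inP[j] && w(j) > tol) cand.push_back(j);
    }
    bool removed = false;
    int added = 0;
    for (uword ci = 0; ci < cand.size() && !removed; ++ci) {
      if (inP[cand[ci]]) continue;
      if (++it > max_iter) {
        res.converged = false; outer_done = true; break;
      }
      if (!F.add(cand[ci])) continue;
      P.push_back(cand[ci]);
      inP[cand[ci]] = 1;
      ++added;

      // inner loop: restore feasibility of the passive LS solution
      while (true) {
        vec z(P.size());
        for (uword i = 0; i < P.size(); ++i) z(i) = Atb(P[i]);
        F.solve_normal(z);
        bool ok = true;
        double alpha = 1.0;
        sword drop = -1;
        for (uword i = 0; i < P.size(); ++i) {
          if (z(i) <= 0) {
            double xi = x(P[i]);
            double step = xi / (xi - z(i));
            if (step < alpha) { alpha = step; drop = i; }
            ok = false;
          }
        }
        if (ok) {
          for (uword i = 0; i < P.size(); ++i) x(P[i]) = z(i);
          break;
        }
        if (++it > max_iter) {
          res.converged = false; outer_done = true; break;
        }
        for (uword i = 0; i < P.size(); ++i)
          x(P[i]) = x(P[i]) + alpha * (z(i) - x(P[i]));
        for (sword i = (sword)P.size() - 1; i >= 0; --i) {
          if (x(P[i]) <= 1e-14 || i == drop) {
            x(P[i]) = 0.0; inP[P[i]] = 0;
            F.remove((uword)i);
            P.erase(P.begin() + i);
            removed = true;
          }
        }
        if (P.empty()) break;
      }
    }
    if (!res.converged) break;
    if (added == 0 && !removed) break;  // numerical floor: nothing movable

    // exact gradient refresh
    vec xP(P.size());
    for (uword i = 0; i < P.size(); ++i) xP(i) = x(P[i]);
    vec r = F.ap_times(xP) - b;
    res.resid = r;
    if (stop_resid > 0 && norm(r, 2) < stop_resid) {
      res.status = 2;
      break;
    }
    w = -(A.t() * r);
  }

  if (res.resid.n_elem == 0) {
    vec xP(P.size());
    for (uword i = 0; i < P.size(); ++i) xP(i) = x(P[i]);
    res.resid = F.ap_times(xP) - b;
  }
  res.x = x;
  res.rnorm = norm(res.resid, 2);
  res.iters = it;
  return res;
}

//' @noRd
// [[Rcpp::export(name = ".nnls_cpp")]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    double tol = -1.0, int max_iter = -1,
                    double stop_resid = 0.0, bool certificate = false) {
  NNLSResult r = nnls_core(A, b, tol, max_iter, stop_resid, certificate);
  return Rcpp::List::create(
      Rcpp::Named("x") = r.x,
      Rcpp::Named("resid") = r.resid,
      Rcpp::Named("rnorm") = r.rnorm,
      Rcpp::Named("iterations") = r.iters,
      Rcpp::Named("converged") = r.converged,
      Rcpp::Named("status") = r.status);
}

// Batched mean-field inner problem over Gaussian probes.
//
// For each probe T (row of Tmat, length D+1) solve
//   min_V ||V - T||^2  s.t.  S V >= 0  (rows of S span the sample set)
// through the NNLS dual  min_{l>=0} ||S' l + T||^2,  V = T + S' l,
// and accumulate the anchor-point statistics used for R_M and D_M.
//
// Returns per probe: F (objective), r2 = ||dS~||^2, dm = (dT . dS^)^2,
// interior flag (F == 0 within tolerance) and sum(l).
// [[Rcpp::export(name = ".inner_batch_cpp")]]
Rcpp::List inner_batch_cpp(const arma::mat& S, const arma::mat& Tmat,
                           double ftol = 1e-10) {
  const uword d1 = S.n_cols;       // D + 1
  const uword np = Tmat.n_rows;
  if (Tmat.n_cols != d1) Rcpp::stop("probe dimension mismatch");
  mat St = S.t();                  // (D+1) x M

  vec F(np), r2(np), dm(np), lsum(np);
  ivec interior(np), ok(np);

  for (uword p = 0; p < np; ++p) {
    vec T = Tmat.row(p).t();
    NNLSResult r = nnls_core(St, -T, -1.0, -1, 0.0, false);
    ok(p) = r.converged ? 1 : 0;
    // resid = St * l - (-T) = St*l + T = V
    vec V = r.resid;
    double f = dot(V - T, V - T);
    F(p) = f;
    lsum(p) = accu(r.x);
    if (f <= ftol || lsum(p) <= 0) {
      interior(p) = 1;
      r2(p) = 0.0; dm(p) = 0.0;
      F(p) = (f <= ftol) ? 0.0 : f;
      continue;
    }
    interior(p) = 0;
    // anchor in normalized coordinates: s~ = S' l / sum(l); last coord = 1
    vec anchor = (St * r.x) / lsum(p);
    vec dS = anchor;
    dS(d1 - 1) = 0.0;              // subtract the center S0 = e_{D+1}
    double nrm2 = dot(dS, dS);
    r2(p) = nrm2;
    if (nrm2 > 1e-24 && d1 > 1) {
      vec dT = T; dT(d1 - 1) = 0.0;
      double proj = dot(dT, dS) / std::sqrt(nrm2);
      dm(p) = proj * proj;
    } else {
      dm(p) = 0.0;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("F") = F, Rcpp::Named("r2") = r2, Rcpp::Named("dm") = dm,
      Rcpp::Named("lambda_sum") = lsum,
      Rcpp::Named("interior") = interior, Rcpp::Named("converged") = ok);
}
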