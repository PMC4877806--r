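// Likelihood core for the binomial admixture model.
//
// Parameterization: X (N x M) holds the effective success count per entry
// (the allele count for diploid entries, half the hemizygote-coded count for
// haploid ones), D (N x M) the number of binomial draws (2 diploid, 1
// haploid, 0 missing/skip).  Q (N x K) are simplex rows of ancestry
// proportions, P (K x M) ancestral allele frequencies.  Entries with D = 0
// carry X = 0 and drop out of every sum below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double P_LO = 1e-6;
static const double P_HI = 1.0 - 1e-6;

static inline mat clamp_freq(const mat& P) {
  return clamp(P, P_LO, P_HI);
}

// [[Rcpp::export]]
double cpp_loglik(const arma::mat& X, const arma::mat& D,
                  const arma::mat& Q, const arma::mat& P) {
  mat Pc = clamp_freq(P);
  mat pi = Q * Pc;
  return accu(X % log(pi) + (D - X) % log(1.0 - pi));
}

// One EM sweep over Q with P held fixed.  Rows with no observed data
// (sum(D) == 0) are returned unchanged; the wrapper warns about them.
// [[Rcpp::export]]
arma::mat cpp_update_Q(const arma::mat& X, const arma::mat& D,
                       const arma::mat& Q, const arma::mat& P) {
  mat Pc = clamp_freq(P);
  mat pi = Q * Pc;
  mat A = X / pi;
  mat B = (D - X) / (1.0 - pi);
  mat S = A * Pc.t() + B * (1.0 - Pc).t();   // N x K
  vec Di = sum(D, 1);
  mat Qn = Q % S;
  for (uword i = 0; i < Qn.n_rows; ++i) {
    double s = accu(Qn.row(i));
    if (Di(i) <= 0.0 || !(s > 0.0)) {
      Qn.row(i) = Q.row(i);
    } else {
      Qn.row(i) /= s;
    }
  }
  return Qn;
}

// One EM sweep over P with Q held fixed.  Columns with no observed data are
// returned unchanged.
// [[Rcpp::export]]
arma::mat cpp_update_P(const arma::mat& X, const arma::mat& D,
                       const arma::mat& Q, const arma::mat& P) {
  mat Pc = clamp_freq(P);
  mat pi = Q * Pc;
  mat A = X / pi;
  mat B = (D - X) / (1.0 - pi);
  mat Anum = Pc % (Q.t() * A);               // K x M
  mat Bnum = (1.0 - Pc) % (Q.t() * B);
  mat Pn(size(Pc));
  for (uword j = 0; j < Pn.n_cols; ++j) {
    for (uword k = 0; k < Pn.n_rows; ++k) {
      double den = Anum(k, j) + Bnum(k, j);
      Pn(k, j) = (den > 0.0) ? Anum(k, j) / den : Pc(k, j);
    }
  }
  return clamp_freq(Pn);
}

static inline double row_ll(const rowvec& x, const rowvec& d,
                            const rowvec& q, const mat& Pc) {
  rowvec pi = q * Pc;
  return accu(x % log(pi) + (d - x) % log(1.0 - pi));
}

static inline rowvec row_em(const rowvec& x, const rowvec& d,
                            const rowvec& q, const mat& Pc,
                            const mat& Pt, const mat& P1t, double Di) {
  rowvec pi = q * Pc;
  rowvec a = x / pi;
  rowvec b = (d - x) / (1.0 - pi);
  rowvec s = a * Pt + b * P1t;               // 1 x K
  rowvec qn = (q % s) / Di;
  double tot = accu(qn);
  if (!(tot > 0.0)) return q;
  return qn / tot;
}

static inline rowvec simplex_project(const rowvec& q) {
  rowvec qp = clamp(q, 1e-12, datum::inf);
  return qp / accu(qp);
}

// Per-individual maximization of the mixed binomial likelihood over the
// ancestry simplex with P fixed (projection mode).  Each row is optimized
// independently from the uniform start by monotone EM, optionally
// accelerated with a safeguarded squared-extrapolation step (fall back to
// the plain double EM step whenever extrapolation does not improve the row
// log-likelihood).  Convergence is per row: absolute log-likelihood
// improvement per outer cycle below `tol`.
// [[Rcpp::export]]
Rcpp::List cpp_project(const arma::mat& X, const arma::mat& D,
                       const arma::mat& P, double tol, int max_iter,
                       bool accel) {
  const uword N = X.n_rows;
  const uword K = P.n_rows;
  mat Pc = clamp_freq(P);
  mat Pt = Pc.t();                 // M x K
  mat P1t = (1.0 - Pc).t();
  mat Q(N, K);
  ivec iters(N, fill::zeros);
  ivec conv(N, fill::zeros);
  uvec empty_rows(N, fill::zeros);

  for (uword i = 0; i < N; ++i) {
    rowvec x = X.row(i);
    rowvec d = D.row(i);
    double Di = accu(d);
    rowvec q(K);
    q.fill(1.0 / K);
    if (Di <= 0.0) {
      Q.row(i) = q;
      empty_rows(i) = 1;
      conv(i) = 1;
      continue;
    }
    double ll = row_ll(x, d, q, Pc);
    int sweeps = 0;
    bool converged = false;
    double step_max = 4.0;
    while (sweeps < max_iter) {
      rowvec q1 = row_em(x, d, q, Pc, Pt, P1t, Di);
      rowvec q2 = row_em(x, d, q1, Pc, Pt, P1t, Di);
      sweeps += 2;
      rowvec qn = q2;
      if (accel) {
        rowvec r = q1 - q;
        rowvec v = q2 - 2.0 * q1 + q;
        double vn = accu(v % v);
        if (vn > 1e-28) {
          double alpha = -std::sqrt(accu(r % r) / vn);
          bool capped = false;
          if (alpha < -step_max) { alpha = -step_max; capped = true; }
          if (alpha > -1.0) alpha = -1.0;
          rowvec qs = simplex_project(q - 2.0 * alpha * r + alpha * alpha * v);
          rowvec q3 = row_em(x, d, qs, Pc, Pt, P1t, Di);
          ++sweeps;
          if (row_ll(x, d, q3, Pc) >= row_ll(x, d, q2, Pc)) {
            qn = q3;
            if (capped) step_max *= 4.0;
          }
        }
      }
      double ll_new = row_ll(x, d, qn, Pc);
      q = qn;
      if (ll_new - ll < tol) {
        ll = ll_new;
        converged = true;
        break;
      }
      ll = ll_new;
    }
    Q.row(i) = q;
    iters(i) = sweeps;
    conv(i) = converged ? 1 : 0;
  }

  return Rcpp::List::create(Rcpp::Named("Q") = Q,
                            Rcpp::Named("sweeps") = iters,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("empty_rows") = empty_rows);
}

// Full block-relaxation fit loop (used by fit_unsupervised).  One outer
// cycle = Q sweep + P sweep; with accel, a safeguarded squared-extrapolation
// step with a growing step cap is layered on top and kept only when it does
// not lower the log-likelihood, so the recorded trace is non-decreasing.
static void em_cycle_mats(const mat& X, const mat& D, const vec& Di,
                          const mat& Q, const mat& P, mat& Qn, mat& Pn) {
  mat pi = Q * P;
  mat A = X / pi;
  mat B = (D - X) / (1.0 - pi);
  mat S = A * P.t() + B * (1.0 - P).t();
  Qn = Q % S;
  for (uword i = 0; i < Qn.n_rows; ++i) {
    double s = accu(Qn.row(i));
    if (Di(i) <= 0.0 || !(s > 0.0)) Qn.row(i) = Q.row(i);
    else Qn.row(i) /= s;
  }
  pi = Qn * P;
  A = X / pi;
  B = (D - X) / (1.0 - pi);
  mat Anum = P % (Qn.t() * A);
  mat Bnum = (1.0 - P) % (Qn.t() * B);
  Pn.set_size(size(P));
  for (uword j = 0; j < Pn.n_cols; ++j) {
    for (uword k = 0; k < Pn.n_rows; ++k) {
      double den = Anum(k, j) + Bnum(k, j);
      Pn(k, j) = (den > 0.0) ? Anum(k, j) / den : P(k, j);
    }
  }
  Pn = clamp(Pn, P_LO, P_HI);
}

// [[Rcpp::export]]
Rcpp::List cpp_fit(const arma::mat& X, const arma::mat& D,
                   const arma::mat& Q0, const arma::mat& P0,
                   double tol, int max_iter, bool accel) {
  mat Q = Q0;
  mat P = clamp(P0, P_LO, P_HI);
  vec Di = sum(D, 1);
  double ll = cpp_loglik(X, D, Q, P);
  std::vector<double> trace;
  trace.push_back(ll);
  int n_iter = 0;
  bool converged = false;
  double step_max = 4.0;

  mat Q1, P1, Q2, P2, Q3, P3;
  while (n_iter < max_iter) {
    em_cycle_mats(X, D, Di, Q, P, Q1, P1);
    n_iter += 2;
    mat* Qacc = &Q1;
    mat* Pacc = &P1;
    double ll_acc;
    if (accel) {
      em_cycle_mats(X, D, Di, Q1, P1, Q2, P2);
      n_iter += 2;
      double ll2 = cpp_loglik(X, D, Q2, P2);
      Qacc = &Q2; Pacc = &P2; ll_acc = ll2;
      mat rQ = Q1 - Q, rP = P1 - P;
      mat vQ = Q2 - 2.0 * Q1 + Q, vP = P2 - 2.0 * P1 + P;
      double vn = accu(vQ % vQ) + accu(vP % vP);
      if (vn > 1e-28) {
        double alpha = -std::sqrt((accu(rQ % rQ) + accu(rP % rP)) / vn);
        bool capped = false;
        if (alpha < -step_max) { alpha = -step_max; capped = true; }
        if (alpha > -1.0) alpha = -1.0;
        mat Qs = Q - 2.0 * alpha * rQ + alpha * alpha * vQ;
        for (uword i = 0; i < Qs.n_rows; ++i) {
          rowvec qi = clamp(Qs.row(i), 1e-12, datum::inf);
          Qs.row(i) = qi / accu(qi);
        }
        mat Ps = clamp(P - 2.0 * alpha * rP + alpha * alpha * vP, P_LO, P_HI);
        em_cycle_mats(X, D, Di, Qs, Ps, Q3, P3);
        n_iter += 2;
        double ll3 = cpp_loglik(X, D, Q3, P3);
        if (ll3 >= ll2) {
          Qacc = &Q3; Pacc = &P3; ll_acc = ll3;
          if (capped) step_max *= 4.0;
        }
      }
    } else {
      ll_acc = cpp_loglik(X, D, Q1, P1);
    }
    Q = *Qacc;
    P = *Pacc;
    trace.push_back(ll_acc);
    if (ll_acc - ll < tol) {
      converged = true;
      ll = ll_acc;
      break;
    }
    ll = ll_acc;
  }

  return Rcpp::List::create(Rcpp::Named("Q") = Q,
                            Rcpp::Named("P") = P,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("n_iter") = n_iter);
}
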