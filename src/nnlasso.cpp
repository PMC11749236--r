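#include <Rcpp.h>
using namespace Rcpp;

// Nonnegative lasso on the gene-identity + system-membership design:
//   minimize (1/(2n)) * ||y - I w - H v||^2 + lambda * (sum(w) + sum(v))
//   subject to w >= 0, v >= 0
// I is the n x n identity; H is binary n x p given as 0-based member index
// lists per system column. Solved by cyclic coordinate descent with exact
// single-coordinate minimization and warm starts along a descending lambda
// grid. Columns are not standardized (binary design; system-size semantics
// must be preserved).

namespace {

struct Problem {
  int n, p;
  std::vector<std::vector<int>> members;  // per system, gene indices
  std::vector<double> colnorm2;           // per system, member count
};

Problem make_problem(int n, const List &members) {
  Problem pr;
  pr.n = n;
  pr.p = members.size();
  pr.members.resize(pr.p);
  pr.colnorm2.resize(pr.p);
  for (int c = 0; c < pr.p; ++c) {
    IntegerVector m = members[c];
    pr.members[c].assign(m.begin(), m.end());
    pr.colnorm2[c] = (double)m.size();
  }
  return pr;
}

// residual r = y - w - H v, recomputed from scratch
void recompute_residual(const Problem &pr, const std::vector<double> &y,
                        const std::vector<double> &w,
                        const std::vector<double> &v, std::vector<double> &r) {
  for (int i = 0; i < pr.n; ++i) r[i] = y[i] - w[i];
  for (int c = 0; c < pr.p; ++c) {
    if (v[c] != 0.0)
      for (int i : pr.members[c]) r[i] -= v[c];
  }
}

// one pass over the chosen coordinates; returns max absolute update
double sweep(const Problem &pr, double lambda, std::vector<double> &w,
             std::vector<double> &v, std::vector<double> &r,
             bool active_only) {
  const double n = (double)pr.n;
  double maxdel = 0.0;
  for (int g = 0; g < pr.n; ++g) {
    if (active_only && w[g] == 0.0) continue;
    // X_g = e_g, ||X_g||^2 = 1
    double grad = r[g] / n;  // X_g^T r / n
    double bnew = (grad + w[g] / n - lambda) * n;  // a = 1/n
    if (bnew < 0.0) bnew = 0.0;
    double del = bnew - w[g];
    if (del != 0.0) {
      w[g] = bnew;
      r[g] -= del;
      if (std::abs(del) > maxdel) maxdel = std::abs(del);
    }
  }
  for (int c = 0; c < pr.p; ++c) {
    if (active_only && v[c] == 0.0) continue;
    if (pr.colnorm2[c] == 0.0) continue;
    long double xr = 0.0L;
    for (int i : pr.members[c]) xr += r[i];
    double a = pr.colnorm2[c] / n;
    double bnew = ((double)xr / n + a * v[c] - lambda) / a;
    if (bnew < 0.0) bnew = 0.0;
    double del = bnew - v[c];
    if (del != 0.0) {
      v[c] = bnew;
      for (int i : pr.members[c]) r[i] -= del;
      if (std::abs(del) > maxdel) maxdel = std::abs(del);
    }
  }
  return maxdel;
}

// max KKT violation: for beta_j > 0, |X_j^T r / n - lambda|;
// for beta_j = 0, max(0, X_j^T r / n - lambda)
double kkt_violation(const Problem &pr, double lambda,
                     const std::vector<double> &w, const std::vector<double> &v,
                     const std::vector<double> &r) {
  const double n = (double)pr.n;
  double viol = 0.0;
  for (int g = 0; g < pr.n; ++g) {
    double grad = r[g] / n;
    double d = (w[g] > 0.0) ? std::abs(grad - lambda) : grad - lambda;
    if (d > viol) viol = d;
  }
  for (int c = 0; c < pr.p; ++c) {
    if (pr.colnorm2[c] == 0.0) continue;
    long double xr = 0.0L;
    for (int i : pr.members[c]) xr += r[i];
    double grad = (double)xr / n;
    double d = (v[c] > 0.0) ? std::abs(grad - lambda) : grad - lambda;
    if (d > viol) viol = d;
  }
  return viol;
}

void solve_lambda(const Problem &pr, double lambda, std::vector<double> &w,
                  std::vector<double> &v, std::vector<double> &r, double tol,
                  int max_sweeps) {
  // coefficient-change threshold for the cheap inner loop; the exit
  // criterion proper is the KKT violation
  const double dtol = tol;
  for (int it = 0; it < max_sweeps; ++it) {
    double delta = sweep(pr, lambda, w, v, r, false);
    if (delta > dtol) {
      for (int k = 0; k < max_sweeps; ++k) {
        if (sweep(pr, lambda, w, v, r, true) <= dtol) break;
      }
    }
    if (kkt_violation(pr, lambda, w, v, r) <= tol) return;
  }
}

void path_S(const Problem &pr, const std::vector<double> &y,
            const NumericVector &lambdas, double tol, int max_sweeps,
            std::vector<double> &S) {
  int L = lambdas.size();
  std::vector<double> w(pr.n, 0.0), v(pr.p, 0.0), r(pr.n);
  S.assign(pr.p, 0.0);
  for (int l = 0; l < L; ++l) {
    if (l % 64 == 0) recompute_residual(pr, y, w, v, r);
    solve_lambda(pr, lambdas[l], w, v, r, tol, max_sweeps);
    double total = 0.0;
    for (int g = 0; g < pr.n; ++g) total += w[g];
    for (int c = 0; c < pr.p; ++c) total += v[c];
    if (total > 1e-12) {
      for (int c = 0; c < pr.p; ++c) {
        double frac = v[c] / total;
        if (frac > S[c]) S[c] = frac;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".nnlasso_path_cpp")]]
List nnlasso_path_cpp(NumericVector y, List members, NumericVector lambdas,
                      double tol = 1e-9, int max_sweeps = 10000) {
  Problem pr = make_problem(y.size(), members);
  int L = lambdas.size();
  NumericMatrix W(pr.n, L), V(pr.p, L);
  NumericVector kkt(L);
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> w(pr.n, 0.0), v(pr.p, 0.0), r(pr.n);
  for (int l = 0; l < L; ++l) {
    recompute_residual(pr, yv, w, v, r);
    solve_lambda(pr, lambdas[l], w, v, r, tol, max_sweeps);
    kkt[l] = kkt_violation(pr, lambdas[l], w, v, r);
    for (int g = 0; g < pr.n; ++g) W(g, l) = w[g];
    for (int c = 0; c < pr.p; ++c) V(c, l) = v[c];
  }
  return List::create(_["W"] = W, _["V"] = V, _["kkt"] = kkt);
}

// S(c) per row-permutation of H. perms is n x n_perm, 0-based; permuted
// membership row i of H is the original row perms(i, k), i.e. system c's
// member set becomes the preimage of its original member set.
// [[Rcpp::export(name = ".hisig_perm_S_cpp")]]
NumericMatrix hisig_perm_S_cpp(NumericVector y, List members,
                               NumericVector lambdas, IntegerMatrix perms,
                               double tol = 1e-9, int max_sweeps = 10000) {
  Problem pr = make_problem(y.size(), members);
  int n_perm = perms.ncol();
  NumericMatrix out(n_perm, pr.p);
  std::vector<double> yv(y.begin(), y.end());
  std::vector<int> inv(pr.n);
  Problem pp = pr;
  std::vector<double> S;
  for (int k = 0; k < n_perm; ++k) {
    for (int i = 0; i < pr.n; ++i) inv[perms(i, k)] = i;
    for (int c = 0; c < pr.p; ++c) {
      for (size_t j = 0; j < pr.members[c].size(); ++j)
        pp.members[c][j] = inv[pr.members[c][j]];
    }
    path_S(pp, yv, lambdas, tol, max_sweeps, S);
    for (int c = 0; c < pr.p; ++c) out(k, c) = S[c];
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Observed-path S without storing the full W/V matrices.
// [[Rcpp::export(name = ".hisig_S_cpp")]]
NumericVector hisig_S_cpp(NumericVector y, List members, NumericVector lambdas,
                          double tol = 1e-9, int max_sweeps = 10000) {
  Problem pr = make_problem(y.size(), members);
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> S;
  path_S(pr, yv, lambdas, tol, max_sweeps, S);
  return NumericVector(S.begin(), S.end());
}
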