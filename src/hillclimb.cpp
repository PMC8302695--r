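// Greedy hill-climbing structure search for linear-Gaussian Bayesian
// networks under a decomposable Gaussian BIC score. Family scores are
// computed from the precomputed cross-product matrix of [1, X], so each
// candidate operator costs one small symmetric solve.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

// Maximized Gaussian log-likelihood minus BIC penalty for one family.
// M = crossprod(cbind(1, X)); child/parents are 0-based column indices of X.
double family_score(const arma::mat& M, int n, int child,
                    const std::vector<int>& parents) {
  const int k = static_cast<int>(parents.size());
  if (n < k + 2) return NEG_INF;  // family larger than the data can support
  arma::uvec idx(k + 1);
  idx[0] = 0;
  for (int i = 0; i < k; ++i) idx[i + 1] = parents[i] + 1;
  const arma::uword c = child + 1;
  arma::mat Sxx = M.submat(idx, idx);
  arma::vec Sxy(k + 1);
  for (int i = 0; i <= k; ++i) Sxy[i] = M(idx[i], c);
  arma::vec beta;
  const bool ok = arma::solve(beta, Sxx, Sxy,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
  if (!ok) return NEG_INF;  // singular family: collinear parents
  double rss = M(c, c) - arma::dot(Sxy, beta);
  if (!std::isfinite(rss)) return NEG_INF;
  if (rss < 0.0) rss = 0.0;
  const double sigma2 = std::max(rss / n, 1e-12);
  const double loglik = -0.5 * n * (std::log(2.0 * M_PI * sigma2) + 1.0);
  return loglik - 0.5 * (k + 2) * std::log(static_cast<double>(n));
}

// Is there a directed path from `from` to `to` in adjacency A?
bool has_path(const std::vector<std::vector<bool>>& A, int from, int to) {
  const int p = static_cast<int>(A.size());
  std::vector<bool> seen(p, false);
  std::vector<int> stack{from};
  seen[from] = true;
  while (!stack.empty()) {
    const int u = stack.back();
    stack.pop_back();
    if (u == to) return true;
    for (int v = 0; v < p; ++v) {
      if (A[u][v] && !seen[v]) {
        seen[v] = true;
        stack.push_back(v);
      }
    }
  }
  return false;
}

std::vector<int> parents_of(const std::vector<std::vector<bool>>& A, int child) {
  std::vector<int> out;
  for (int i = 0; i < static_cast<int>(A.size()); ++i) {
    if (A[i][child]) out.push_back(i);
  }
  return out;
}

std::vector<int> with_parent(std::vector<int> pa, int add) {
  pa.push_back(add);
  std::sort(pa.begin(), pa.end());
  return pa;
}

std::vector<int> without_parent(const std::vector<int>& pa, int drop) {
  std::vector<int> out;
  for (int v : pa) if (v != drop) out.push_back(v);
  return out;
}

}  // namespace

// Greedy search with operators add/delete/reverse. Ties are broken
// lexicographically on (operator kind: add < delete < reverse, then the
// lexicographic rank of the parent name, then of the child name), so the
// result is deterministic and independent of column order.
// [[Rcpp::export(name = ".hc_search")]]
Rcpp::List hc_search(const arma::mat& X,
                     const Rcpp::LogicalMatrix& blacklist,
                     const Rcpp::LogicalMatrix& whitelist,
                     const Rcpp::LogicalMatrix& start,
                     const Rcpp::IntegerVector& name_rank,
                     const int max_iter) {
  const int n = static_cast<int>(X.n_rows);
  const int p = static_cast<int>(X.n_cols);
  arma::mat Z(n, p + 1);
  Z.col(0).ones();
  Z.cols(1, p) = X;
  const arma::mat M = Z.t() * Z;

  std::vector<std::vector<bool>> A(p, std::vector<bool>(p, false));
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) {
      if (whitelist(i, j) || start(i, j)) A[i][j] = true;
    }
  }

  std::vector<double> fam(p);
  for (int j = 0; j < p; ++j) fam[j] = family_score(M, n, j, parents_of(A, j));

  // toggle[i][j]: score of family j with parent i added (if absent) or
  // removed (if present), given j's other parents; invalidated whenever j's
  // parent set changes. Avoids rescoring untouched families each sweep.
  std::vector<std::vector<double>> toggle(p, std::vector<double>(p));
  std::vector<bool> fresh(p, false);
  auto refresh_child = [&](int j) {
    if (fresh[j]) return;
    const std::vector<int> pa = parents_of(A, j);
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      toggle[i][j] = A[i][j]
          ? family_score(M, n, j, without_parent(pa, i))
          : (blacklist(i, j) ? NEG_INF
                             : family_score(M, n, j, with_parent(pa, i)));
    }
    fresh[j] = true;
  };

  const double eps = 1e-9;
  int iter = 0;
  while (iter++ < max_iter) {
    for (int j = 0; j < p; ++j) refresh_child(j);
    double best_delta = eps;
    int best_kind = -1, best_i = -1, best_j = -1;
    double best_fam_j = 0.0, best_fam_i = 0.0;

    auto consider = [&](int kind, int i, int j, double delta,
                        double new_fam_j, double new_fam_i) {
      if (!std::isfinite(delta) || delta <= eps) return;
      if (best_kind >= 0) {
        // operators whose gains agree to within rounding error (e.g. the
        // two orientations of a score-equivalent edge) count as tied and
        // fall through to the lexicographic tie-break
        const double tol = 1e-8 * (1.0 + std::fabs(best_delta));
        if (delta < best_delta - tol) return;
        if (delta <= best_delta + tol) {
          if (kind > best_kind) return;
          if (kind == best_kind) {
            if (name_rank[i] > name_rank[best_i]) return;
            if (name_rank[i] == name_rank[best_i] &&
                name_rank[j] >= name_rank[best_j]) return;
          }
        }
      }
      if (delta > best_delta) best_delta = delta;
      best_kind = kind;
      best_i = i;
      best_j = j;
      best_fam_j = new_fam_j;
      best_fam_i = new_fam_i;
    };

    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (i == j) continue;
        if (!A[i][j]) {
          // add i -> j
          if (blacklist(i, j)) continue;
          if (has_path(A, j, i)) continue;  // would create a cycle
          const double s = toggle[i][j];
          consider(0, i, j, s - fam[j], s, 0.0);
        } else {
          // delete i -> j
          if (!whitelist(i, j)) {
            const double s = toggle[i][j];
            consider(1, i, j, s - fam[j], s, 0.0);
          }
          // reverse i -> j (becomes j -> i); j is not currently a parent of
          // i (acyclicity), so toggle[j][i] is the add-j score for family i
          if (!whitelist(i, j) && !blacklist(j, i)) {
            A[i][j] = false;
            const bool acyclic = !has_path(A, i, j);
            A[i][j] = true;
            if (acyclic) {
              const double sj = toggle[i][j];
              const double si = toggle[j][i];
              consider(2, i, j, (sj + si) - (fam[j] + fam[i]), sj, si);
            }
          }
        }
      }
    }

    if (best_kind < 0) break;  // local optimum
    if (best_kind == 0) {
      A[best_i][best_j] = true;
      fam[best_j] = best_fam_j;
      fresh[best_j] = false;
    } else if (best_kind == 1) {
      A[best_i][best_j] = false;
      fam[best_j] = best_fam_j;
      fresh[best_j] = false;
    } else {
      A[best_i][best_j] = false;
      A[best_j][best_i] = true;
      fam[best_j] = best_fam_j;
      fam[best_i] = best_fam_i;
      fresh[best_j] = false;
      fresh[best_i] = false;
    }
  }

  Rcpp::LogicalMatrix out(p, p);
  double total = 0.0;
  for (int j = 0; j < p; ++j) total += fam[j];
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) out(i, j) = A[i][j];
  }
  return Rcpp::List::create(Rcpp::Named("amat") = out,
                            Rcpp::Named("score") = total,
                            Rcpp::Named("iterations") = iter - 1);
}
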