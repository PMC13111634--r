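// Elastic-net machinery for the two-group epigenetic clock.
//
// The grid search evaluates, for every (slope, intercept, alpha) candidate,
// a full outer leave-one-out loop: each sample is predicted by an elastic
// net trained on the remaining samples, with the penalty strength chosen by
// leave-one-out cross-validation *inside* the training set.  The inner LOO
// is computed with the closed-form hat-matrix identity of the active-set
// restricted problem (exact for ridge; exact for the elastic net whenever
// the active set is stable under deletion of one observation), which is
// what makes grid x outer-LOO x inner-LOO x lambda-path feasible.
//
// Predictor columns are centred within each training set but not
// variance-scaled (they are PC scores; see get_std); the response is
// centred via an unpenalised intercept.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct TrainStd {
  // standardisation of the training set excluding one row (or none)
  int excl;            // excluded row index, -1 for full data
  uvec rows;           // training row indices
  vec m, s;            // column means / sds (1/n variance)
  mat G;               // standardised Gram  Xs'Xs / n'
  // ridge eigen machinery (built lazily)
  bool eig_ready = false;
  vec eval;
  mat evec;            // G = evec diag(eval) evec'
  mat W, W2;           // W = Xs * evec (n' x p), W2 = W^2 elementwise
};

struct HKey {
  uint64_t mask;
  int lam_idx;
  int alpha_id;
  bool operator==(const HKey& o) const {
    return mask == o.mask && lam_idx == o.lam_idx && alpha_id == o.alpha_id;
  }
};
struct HKeyHash {
  size_t operator()(const HKey& k) const {
    uint64_t h = k.mask;
    h ^= (uint64_t)k.lam_idx * 0x9e3779b97f4a7c15ULL;
    h ^= (uint64_t)(k.alpha_id + 7) * 0xc2b2ae3d27d4eb4fULL;
    h ^= h >> 29; h *= 0xbf58476d1ce4e5b9ULL; h ^= h >> 32;
    return (size_t)h;
  }
};

// Log-spaced penalty path.  The top is the smallest penalty nullifying all
// coefficients (scaled by 1/alpha; capped for ridge), the bottom is anchored
// at max|c| * min_ratio for every alpha so that the ridge path actually
// reaches the lightly-penalised regime instead of staying at 1000x max|c|.
vec lambda_path(const vec& c, double alpha, int nlambda, double min_ratio) {
  double amax = std::max(alpha, 1e-3);
  double cmax = std::max(max(abs(c)), 1e-12);
  double lmax = cmax / amax;
  double lmin = std::min(cmax * min_ratio, lmax * 0.5);
  vec path(nlambda);
  double lr = std::log(lmax);
  double step = (std::log(lmin) - lr) / (nlambda - 1);
  for (int l = 0; l < nlambda; ++l) path[l] = std::exp(lr + step * l);
  return path;
}

class EnetEngine {
public:
  mat X;               // n x p raw predictor matrix (PC scores)
  int n, p;
  mat XtX;             // raw X'X
  rowvec csum;         // column sums
  std::vector<TrainStd> st;                 // [0..n-1]: excl i, [n]: full
  std::vector<std::unordered_map<HKey, vec, HKeyHash>> hcache;
  std::vector<std::map<int, vec>> pathcache;  // alpha_id -> lambda path
  size_t hcache_cap = 4000;

  explicit EnetEngine(const mat& X_) : X(X_) {
    n = X.n_rows; p = X.n_cols;
    XtX = X.t() * X;
    csum = sum(X, 0);
    st.resize(n + 1);
    hcache.resize(n + 1);
    pathcache.resize(n + 1);
  }

  TrainStd& get_std(int excl) {
    int idx = excl < 0 ? n : excl;
    TrainStd& t = st[idx];
    if (!t.m.is_empty()) return t;
    t.excl = excl;
    int np = excl < 0 ? n : n - 1;
    uvec rows(np);
    int r = 0;
    for (int k = 0; k < n; ++k) if (k != excl) rows[r++] = k;
    t.rows = rows;
    t.m.set_size(p); t.s.set_size(p);
    mat G(p, p);
    for (int j = 0; j < p; ++j) {
      double sj = csum[j];
      if (excl >= 0) sj -= X(excl, j);
      t.m[j] = sj / np;
    }
    for (int j = 0; j < p; ++j) {
      for (int k = j; k < p; ++k) {
        double v = XtX(j, k);
        if (excl >= 0) v -= X(excl, j) * X(excl, k);
        v = v / np - t.m[j] * t.m[k];
        G(j, k) = v; G(k, j) = v;
      }
    }
    // columns are centred but NOT variance-scaled: the predictors are
    // principal-component scores, whose scale encodes explained variance;
    // equal-scale standardisation would inflate the noise components to
    // the signal component's size and break the ridge end of the path
    for (int j = 0; j < p; ++j) {
      t.s[j] = 1.0;
      if (G(j, j) <= 1e-20) {
        // degenerate column: freeze it out
        G.row(j).zeros(); G.col(j).zeros(); G(j, j) = 1.0;
      }
    }
    t.G = G;
    return t;
  }

  void ensure_eig(TrainStd& t) {
    if (t.eig_ready) return;
    eig_sym(t.eval, t.evec, t.G);
    t.eval.transform([](double v) { return v < 0 ? 0.0 : v; });
    int np = t.rows.n_elem;
    mat Xs(np, p);
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < np; ++k)
        Xs(k, j) = (X(t.rows[k], j) - t.m[j]) / t.s[j];
    }
    t.W = Xs * t.evec;
    t.W2 = square(t.W);
    t.eig_ready = true;
  }

  // correlation-scale inner products of training X with y
  // returns c_j = cov(x_j, y)/sd(x_j) on the training rows, plus ybar
  void make_c(const TrainStd& t, const vec& y, vec& c, double& ybar) const {
    int np = t.rows.n_elem;
    double sy = 0;
    for (int k = 0; k < np; ++k) sy += y[t.rows[k]];
    ybar = sy / np;
    c.set_size(p);
    for (int j = 0; j < p; ++j) {
      double v = 0;
      for (int k = 0; k < np; ++k) v += X(t.rows[k], j) * y[t.rows[k]];
      v = v / np - t.m[j] * ybar;
      c[j] = v / t.s[j];
    }
  }

  // per-training-set lambda path, derived from a reference response so it
  // is shared across grid points and never uses the held-out sample's data
  const vec& path_for(int excl, const vec& y_ref, double alpha, int alpha_id,
                      int nlambda, double min_ratio) {
    auto& m = pathcache[excl < 0 ? n : excl];
    auto it = m.find(alpha_id);
    if (it != m.end()) return it->second;
    TrainStd& t = get_std(excl);
    vec c; double ybar;
    make_c(t, y_ref, c, ybar);
    auto res = m.emplace(alpha_id, lambda_path(c, alpha, nlambda, min_ratio));
    return res.first->second;
  }

  // coordinate descent over a decreasing lambda path (glmnet objective)
  static void cd_path(const mat& G, const vec& c, double alpha,
                      const vec& lambda, mat& B,
                      double tol = 1e-8, int maxit = 2000) {
    int p = G.n_rows, L = lambda.n_elem;
    B.zeros(p, L);
    vec beta(p, fill::zeros);
    vec g = c;  // g_j = c_j - (G beta)_j
    vec diag_g = G.diag();
    double gmax = diag_g.max();
    for (int l = 0; l < L; ++l) {
      double la = lambda[l] * alpha;
      double l2 = lambda[l] * (1.0 - alpha);
      for (int it = 0; it < maxit; ++it) {
        double dmax = 0;
        for (int j = 0; j < p; ++j) {
          double bj = beta[j];
          double u = g[j] + diag_g[j] * bj;
          double nb = 0.0;
          if (u > la) nb = (u - la) / (diag_g[j] + l2);
          else if (u < -la) nb = (u + la) / (diag_g[j] + l2);
          double d = nb - bj;
          if (d != 0.0) {
            beta[j] = nb;
            g -= d * G.col(j);
            // convergence on the fitted-value scale
            double ad = std::fabs(d) * std::sqrt(diag_g[j] / gmax);
            if (ad > dmax) dmax = ad;
          }
        }
        if (dmax < tol) break;
      }
      B.col(l) = beta;
    }
  }

  // hat-matrix diagonal for the active set A at penalty lam2 = lambda(1-alpha)
  // H_kk = 1/n' + xs_k,A' (G_AA + lam2 I)^{-1} xs_k,A / n'
  vec hat_diag(TrainStd& t, const uvec& A, double lam2) {
    int np = t.rows.n_elem;
    int a = A.n_elem;
    vec h(np);
    if (a == 0) { h.fill(1.0 / np); return h; }
    mat M = t.G.submat(A, A);
    M.diag() += lam2 + 1e-10;
    mat L;
    if (!chol(L, M, "lower")) {
      M.diag() += 1e-6;
      if (!chol(L, M, "lower")) { h.fill(1.0 / np); return h; }
    }
    mat Xa(np, a);
    for (int jj = 0; jj < a; ++jj) {
      int j = A[jj];
      for (int k = 0; k < np; ++k)
        Xa(k, jj) = (X(t.rows[k], j) - t.m[j]) / t.s[j];
    }
    mat Z = solve(trimatl(L), Xa.t());  // a x np
    for (int k = 0; k < np; ++k) {
      double q = dot(Z.col(k), Z.col(k));
      h[k] = (1.0 + q) / np;
    }
    return h;
  }

  vec hat_diag_cached(int excl, TrainStd& t, const uvec& A, double lam2,
                      int lam_idx, int alpha_id) {
    if (p > 64) return hat_diag(t, A, lam2);
    uint64_t mask = 0;
    for (unsigned kk = 0; kk < A.n_elem; ++kk) mask |= (1ULL << A[kk]);
    HKey key{mask, lam_idx, alpha_id};
    auto& cache = hcache[excl < 0 ? n : excl];
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    vec h = hat_diag(t, A, lam2);
    if (cache.size() < hcache_cap) cache.emplace(key, h);
    return h;
  }

  // Outer-LOO prediction for sample `excl` with inner ALO lambda selection.
  // Elastic net (alpha > 0) branch.
  double loo_one_enet(int excl, const vec& y, double alpha, const vec& lambda,
                      int alpha_id, int dfmax = 0, int* sel_idx = nullptr) {
    TrainStd& t = get_std(excl);
    int np = t.rows.n_elem;
    vec c; double ybar;
    make_c(t, y, c, ybar);
    mat B;
    cd_path(t.G, c, alpha, lambda, B);
    int L = lambda.n_elem;
    double best_cv = datum::inf;
    int best_l = 0;
    vec ytr(np);
    for (int k = 0; k < np; ++k) ytr[k] = y[t.rows[k]];
    double lam2f = 1.0 - alpha;
    for (int l = 0; l < L; ++l) {
      uvec A = find(abs(B.col(l)) > 0);
      // overfit guard: exclude path points with too many active components
      if (dfmax > 0 && (int)A.n_elem > dfmax) continue;
      // fitted values
      vec fit(np, fill::value(ybar));
      for (unsigned jj = 0; jj < A.n_elem; ++jj) {
        int j = A[jj];
        double b = B(j, l);
        for (int k = 0; k < np; ++k)
          fit[k] += b * (X(t.rows[k], j) - t.m[j]) / t.s[j];
      }
      vec h = hat_diag_cached(excl, t, A, lambda[l] * lam2f, l, alpha_id);
      double cv = 0; bool ok = true;
      for (int k = 0; k < np; ++k) {
        double d = 1.0 - h[k];
        if (d < 1e-8) { ok = false; break; }
        double r = (ytr[k] - fit[k]) / d;
        cv += r * r;
      }
      if (!ok) continue;
      cv /= np;
      if (cv < best_cv) { best_cv = cv; best_l = l; }
    }
    if (sel_idx) *sel_idx = best_l;
    // predict the held-out sample
    double pred = ybar;
    for (int j = 0; j < p; ++j) {
      double b = B(j, best_l);
      if (b != 0.0) pred += b * (X(excl, j) - t.m[j]) / t.s[j];
    }
    return pred;
  }

  // Ridge branch: exact LOO over the whole path via the eigen decomposition.
  double loo_one_ridge(int excl, const vec& y, const vec& lambda,
                       int* sel_idx = nullptr) {
    TrainStd& t = get_std(excl);
    ensure_eig(t);
    int np = t.rows.n_elem;
    vec c; double ybar;
    make_c(t, y, c, ybar);
    vec d = t.evec.t() * c;          // p
    vec ytr(np);
    for (int k = 0; k < np; ++k) ytr[k] = y[t.rows[k]];
    vec qxi = t.evec.t() * ((X.row(excl).t() - t.m) / t.s);
    int L = lambda.n_elem;
    double best_cv = datum::inf, best_pred = ybar;
    int best_l = 0;
    for (int l = 0; l < L; ++l) {
      vec inv = 1.0 / (t.eval + lambda[l]);
      vec e = d % inv;
      vec fit = ybar + t.W * e;
      vec hq = t.W2 * inv;           // n'
      double cv = 0; bool ok = true;
      for (int k = 0; k < np; ++k) {
        double h = (1.0 + hq[k]) / np;
        double dd = 1.0 - h;
        if (dd < 1e-8) { ok = false; break; }
        double r = (ytr[k] - fit[k]) / dd;
        cv += r * r;
      }
      if (!ok) continue;
      cv /= np;
      if (cv < best_cv) {
        best_cv = cv; best_l = l;
        best_pred = ybar + dot(qxi, e);
      }
    }
    if (sel_idx) *sel_idx = best_l;
    return best_pred;
  }

  vec loo_predict(const vec& y, const vec& y_ref, double alpha,
                  int alpha_id, int nlambda, double min_ratio,
                  int dfmax = 0) {
    vec pred(n);
    for (int i = 0; i < n; ++i) {
      const vec& path = path_for(i, y_ref, alpha, alpha_id, nlambda,
                                 min_ratio);
      if (alpha <= 0.0)
        pred[i] = loo_one_ridge(i, y, path);
      else
        pred[i] = loo_one_enet(i, y, alpha, path, alpha_id, dfmax);
    }
    return pred;
  }
};

// Squared correlation of predicted vs transformed age, credited only when
// the orientation is positive: an intercept-only LOO model reproduces the
// held-out response as an affine function with slope -1/(n-1), so a
// near-constant predictor is perfectly *anti*correlated with the response
// and must score zero, not one.
double r2_of(const vec& pred, const vec& y) {
  double sp = stddev(pred), sy = stddev(y);
  if (sp < 1e-12 || sy < 1e-12) return 0.0;
  double r = as_scalar(cor(pred, y));
  if (!std::isfinite(r) || r <= 0.0) return 0.0;
  return r * r;
}

vec transform_ages_cpp(const vec& ages, const vec& zoo, double s, double b) {
  vec t = ages;
  double f = std::exp2(s);
  for (unsigned i = 0; i < t.n_elem; ++i)
    if (zoo[i] > 0.5) t[i] = f * ages[i] + b;
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_grid_search")]]
Rcpp::List cpp_grid_search(const arma::mat& X, const arma::vec& ages,
                           const arma::vec& zoo, const arma::mat& grid,
                           int nlambda, double lambda_min_ratio,
                           int dfmax = 0) {
  EnetEngine eng(X);
  std::map<double, int> alpha_ids;
  int npts = grid.n_rows;
  vec r2(npts);
  for (int g = 0; g < npts; ++g) {
    double s = grid(g, 0), b = grid(g, 1), alpha = grid(g, 2);
    auto it = alpha_ids.find(alpha);
    if (it == alpha_ids.end())
      it = alpha_ids.emplace(alpha, (int)alpha_ids.size()).first;
    vec y = transform_ages_cpp(ages, zoo, s, b);
    vec pred = eng.loo_predict(y, ages, alpha, it->second, nlambda,
                               lambda_min_ratio, dfmax);
    r2[g] = r2_of(pred, y);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("r2") = r2);
}

// [[Rcpp::export(name = ".cpp_loo_predict")]]
Rcpp::List cpp_loo_predict(const arma::mat& X, const arma::vec& y,
                           double alpha, int nlambda,
                           double lambda_min_ratio, int dfmax = 0) {
  EnetEngine eng(X);
  int n = X.n_rows;
  vec pred(n), lam_sel(n);
  for (int i = 0; i < n; ++i) {
    int sel = 0;
    const vec& path = eng.path_for(i, y, alpha, 0, nlambda,
                                   lambda_min_ratio);
    if (alpha <= 0.0) pred[i] = eng.loo_one_ridge(i, y, path, &sel);
    else pred[i] = eng.loo_one_enet(i, y, alpha, path, 0, dfmax, &sel);
    lam_sel[i] = path[sel];
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("lambda") = lam_sel);
}

// Brute-force variant: the inner LOO refits the elastic net for every inner
// fold instead of using the hat-matrix identity.  Used to validate the fast
// path on small problems.
// [[Rcpp::export(name = ".cpp_loo_predict_exact")]]
Rcpp::List cpp_loo_predict_exact(const arma::mat& X, const arma::vec& y,
                                 double alpha, int nlambda,
                                 double lambda_min_ratio) {
  int n = X.n_rows, p = X.n_cols;
  EnetEngine eng(X);
  vec pred(n), lam_sel(n);
  for (int i = 0; i < n; ++i) {
    const vec& path = eng.path_for(i, y, alpha, 0, nlambda,
                                   lambda_min_ratio);
    int L = path.n_elem;
    // inner folds: leave out j as well
    vec cv(L, fill::zeros);
    ivec cnt(L, fill::zeros);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      // standardise over rows excluding {i, j}
      int np = n - 2;
      uvec rows(np); int r = 0;
      for (int k = 0; k < n; ++k) if (k != i && k != j) rows[r++] = k;
      vec m(p), sdv(p);
      mat G(p, p);
      double ybar = 0;
      for (int k = 0; k < np; ++k) ybar += y[rows[k]];
      ybar /= np;
      for (int jj = 0; jj < p; ++jj) {
        double sm = 0;
        for (int k = 0; k < np; ++k) sm += X(rows[k], jj);
        m[jj] = sm / np;
      }
      vec c(p);
      for (int jj = 0; jj < p; ++jj) sdv[jj] = 1.0;
      for (int jj = 0; jj < p; ++jj) {
        for (int kk = jj; kk < p; ++kk) {
          double v = 0;
          for (int k = 0; k < np; ++k) v += X(rows[k], jj) * X(rows[k], kk);
          v = v / np - m[jj] * m[kk];
          G(jj, kk) = v; G(kk, jj) = v;
        }
        if (G(jj, jj) <= 1e-20) {
          G.row(jj).zeros(); G.col(jj).zeros(); G(jj, jj) = 1.0;
        }
      }
      for (int jj = 0; jj < p; ++jj) {
        double v = 0;
        for (int k = 0; k < np; ++k) v += X(rows[k], jj) * y[rows[k]];
        v = v / np - m[jj] * ybar;
        c[jj] = v / sdv[jj];
      }
      mat B;
      EnetEngine::cd_path(G, c, std::max(alpha, 0.0), path, B);
      if (alpha <= 0.0) {
        // ridge closed form per lambda
        for (int l = 0; l < L; ++l) {
          mat M = G; M.diag() += path[l];
          vec beta = solve(M, c);
          double fit = ybar;
          for (int jj = 0; jj < p; ++jj)
            fit += beta[jj] * (X(j, jj) - m[jj]) / sdv[jj];
          double rres = y[j] - fit;
          cv[l] += rres * rres; cnt[l] += 1;
        }
      } else {
        for (int l = 0; l < L; ++l) {
          double fit = ybar;
          for (int jj = 0; jj < p; ++jj) {
            double b = B(jj, l);
            if (b != 0.0) fit += b * (X(j, jj) - m[jj]) / sdv[jj];
          }
          double rres = y[j] - fit;
          cv[l] += rres * rres; cnt[l] += 1;
        }
      }
    }
    int best_l = 0; double best = datum::inf;
    for (int l = 0; l < L; ++l) {
      if (cnt[l] == 0) continue;
      double v = cv[l] / cnt[l];
      if (v < best) { best = v; best_l = l; }
    }
    // refit on all training rows (excluding i) at the chosen lambda
    TrainStd& t = eng.get_std(i);
    vec ci; double ybari;
    eng.make_c(t, y, ci, ybari);
    vec beta;
    if (alpha <= 0.0) {
      mat M = t.G; M.diag() += path[best_l];
      beta = solve(M, ci);
    } else {
      mat B;
      EnetEngine::cd_path(t.G, ci, alpha, path, B);
      beta = B.col(best_l);
    }
    double pr = ybari;
    for (int jj = 0; jj < p; ++jj)
      pr += beta[jj] * (X(i, jj) - t.m[jj]) / t.s[jj];
    pred[i] = pr;
    lam_sel[i] = path[best_l];
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("lambda") = lam_sel);
}

// [[Rcpp::export(name = ".cpp_permute_search")]]
arma::mat cpp_permute_search(const arma::mat& X, const arma::vec& ages,
                             const arma::mat& zoo_perms, const arma::mat& grid,
                             int nlambda, double lambda_min_ratio,
                             int dfmax = 0) {
  EnetEngine eng(X);
  std::map<double, int> alpha_ids;
  int npts = grid.n_rows, P = zoo_perms.n_cols;
  mat r2(npts, P);
  for (int q = 0; q < P; ++q) {
    vec zoo = zoo_perms.col(q);
    for (int g = 0; g < npts; ++g) {
      double s = grid(g, 0), b = grid(g, 1), alpha = grid(g, 2);
      auto it = alpha_ids.find(alpha);
      if (it == alpha_ids.end())
        it = alpha_ids.emplace(alpha, (int)alpha_ids.size()).first;
      vec y = transform_ages_cpp(ages, zoo, s, b);
      vec pred = eng.loo_predict(y, ages, alpha, it->second, nlambda,
                                 lambda_min_ratio, dfmax);
      r2(g, q) = r2_of(pred, y);
    }
    Rcpp::checkUserInterrupt();
  }
  return r2;
}

// Full-data elastic net path fit; coefficients returned on the original
// predictor scale.
// [[Rcpp::export(name = ".cpp_enet_path")]]
Rcpp::List cpp_enet_path(const arma::mat& X, const arma::vec& y,
                         double alpha, const arma::vec& lambda) {
  EnetEngine eng(X);
  TrainStd& t = eng.get_std(-1);
  vec c; double ybar;
  eng.make_c(t, y, c, ybar);
  int p = X.n_cols, L = lambda.n_elem;
  mat Bstd;
  if (alpha <= 0.0) {
    Bstd.set_size(p, L);
    for (int l = 0; l < L; ++l) {
      mat M = t.G; M.diag() += lambda[l];
      Bstd.col(l) = solve(M, c);
    }
  } else {
    EnetEngine::cd_path(t.G, c, alpha, lambda, Bstd);
  }
  mat B(p, L);
  vec b0(L);
  for (int l = 0; l < L; ++l) {
    for (int j = 0; j < p; ++j) B(j, l) = Bstd(j, l) / t.s[j];
    b0[l] = ybar - dot(B.col(l), t.m);
  }
  return Rcpp::List::create(Rcpp::Named("beta") = B,
                            Rcpp::Named("b0") = b0);
}

// Full-data ALO leave-one-out CV curve over a lambda path (used to choose
// alpha/lambda when training on a single group).
// [[Rcpp::export(name = ".cpp_enet_alo_cv")]]
Rcpp::List cpp_enet_alo_cv(const arma::mat& X, const arma::vec& y,
                           double alpha, int nlambda,
                           double lambda_min_ratio) {
  EnetEngine eng(X);
  TrainStd& t = eng.get_std(-1);
  vec c; double ybar;
  eng.make_c(t, y, c, ybar);
  vec path = lambda_path(c, alpha, nlambda, lambda_min_ratio);
  int nn = X.n_rows, p = X.n_cols, L = path.n_elem;
  mat Bstd;
  if (alpha <= 0.0) {
    Bstd.set_size(p, L);
    for (int l = 0; l < L; ++l) {
      mat M = t.G; M.diag() += path[l];
      Bstd.col(l) = solve(M, c);
    }
  } else {
    EnetEngine::cd_path(t.G, c, alpha, path, Bstd);
  }
  vec cvm(L);
  cvm.fill(datum::inf);
  double lam2f = 1.0 - alpha;
  for (int l = 0; l < L; ++l) {
    uvec A = alpha <= 0.0 ? regspace<uvec>(0, p - 1)
                          : find(abs(Bstd.col(l)) > 0);
    vec fit(nn, fill::value(ybar));
    for (unsigned jj = 0; jj < A.n_elem; ++jj) {
      int j = A[jj];
      double b = Bstd(j, l);
      if (b == 0.0 && alpha > 0.0) continue;
      for (int k = 0; k < nn; ++k)
        fit[k] += b * (X(k, j) - t.m[j]) / t.s[j];
    }
    // ridge: lam2 = lambda; elastic net: lam2 = lambda (1 - alpha)
    vec h = eng.hat_diag(t, A, alpha <= 0.0 ? path[l] : path[l] * lam2f);
    double cv = 0; bool ok = true;
    for (int k = 0; k < nn; ++k) {
      double d = 1.0 - h[k];
      if (d < 1e-8) { ok = false; break; }
      double r = (y[k] - fit[k]) / d;
      cv += r * r;
    }
    if (ok) cvm[l] = cv / nn;
  }
  mat B(p, L);
  vec b0(L);
  for (int l = 0; l < L; ++l) {
    for (int j = 0; j < p; ++j) B(j, l) = Bstd(j, l) / t.s[j];
    b0[l] = ybar - dot(B.col(l), t.m);
  }
  return Rcpp::List::create(Rcpp::Named("lambda") = path,
                            Rcpp::Named("cvm") = cvm,
                            Rcpp::Named("beta") = B,
                            Rcpp::Named("b0") = b0);
}
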