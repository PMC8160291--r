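#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Soft-margin SVM dual solver (sequential minimal optimization, Platt-style
// with a deterministic second-choice heuristic).  Takes a precomputed
// kernel matrix so the kernel itself lives in R; returns the dual
// coefficients alpha and the bias b.  The equality constraint
// sum(alpha * y) = 0 holds exactly by construction.

class SMO {
public:
  SMO(const double *K, const double *y, int n, double C, double tol)
      : K_(K), y_(y), C_(C), tol_(tol), n_(n),
        alpha_(n_, 0.0), F_(n_, 0.0), b_(0.0) {}

  double kv(int i, int j) const { return K_[i + (size_t)n_ * j]; }

  // F_i = sum_j alpha_j y_j K_ij  (decision value without bias)
  double error(int i) const { return F_[i] + b_ - y_[i]; }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha_[i1], a2 = alpha_[i2];
    double y1 = y_[i1], y2 = y_[i2];
    double E1 = error(i1), E2 = error(i2);
    double s = y1 * y2;
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C_, C_ + a2 - a1); }
    else       { L = std::max(0.0, a1 + a2 - C_); H = std::min(C_, a1 + a2); }
    if (H - L < 1e-12) return false;
    double k11 = kv(i1, i1), k12 = kv(i1, i2), k22 = kv(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 1e-12) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // flat objective along the constraint: evaluate endpoints
      double f1 = y1 * (E1 + b_) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b_) - s * a1 * k12 - a2 * k22;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double psiL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 + 0.5 * L * L * k22 + s * L * L1 * k12;
      double psiH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 + 0.5 * H * H * k22 + s * H * H1 * k12;
      if (psiL < psiH - 1e-12) a2new = L;
      else if (psiH < psiL - 1e-12) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < 1e-12 * (a2new + a2 + 1e-12)) return false;
    double a1new = a1 + s * (a2 - a2new);
    // bias update from the two examples
    double b1 = b_ - (E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12);
    double b2 = b_ - (E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22);
    if (a1new > 1e-12 && a1new < C_ - 1e-12) b_ = b1;
    else if (a2new > 1e-12 && a2new < C_ - 1e-12) b_ = b2;
    else b_ = 0.5 * (b1 + b2);
    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    for (int j = 0; j < n_; ++j) F_[j] += d1 * kv(i1, j) + d2 * kv(i2, j);
    alpha_[i1] = a1new; alpha_[i2] = a2new;
    return true;
  }

  bool examine(int i2) {
    double y2 = y_[i2], a2 = alpha_[i2], E2 = error(i2);
    double r2 = E2 * y2;
    if ((r2 < -tol_ && a2 < C_ - 1e-12) || (r2 > tol_ && a2 > 1e-12)) {
      // heuristic 1: maximize |E1 - E2| over non-bound alphas
      int best = -1; double bestgap = -1.0;
      for (int j = 0; j < n_; ++j) {
        if (alpha_[j] > 1e-12 && alpha_[j] < C_ - 1e-12) {
          double gap = std::fabs(error(j) - E2);
          if (gap > bestgap) { bestgap = gap; best = j; }
        }
      }
      if (best >= 0 && take_step(best, i2)) return true;
      // heuristic 2: sweep non-bound, then all (deterministic order)
      for (int j = 0; j < n_; ++j)
        if (alpha_[j] > 1e-12 && alpha_[j] < C_ - 1e-12 && take_step(j, i2))
          return true;
      for (int j = 0; j < n_; ++j)
        if (take_step(j, i2)) return true;
    }
    return false;
  }

  void solve_core(int max_iter) {
    int num_changed = 0;
    bool examine_all = true;
    int iter = 0;
    while ((num_changed > 0 || examine_all) && iter < max_iter) {
      ++iter;
      num_changed = 0;
      if (examine_all) {
        for (int i = 0; i < n_; ++i) num_changed += examine(i) ? 1 : 0;
      } else {
        for (int i = 0; i < n_; ++i)
          if (alpha_[i] > 1e-12 && alpha_[i] < C_ - 1e-12)
            num_changed += examine(i) ? 1 : 0;
      }
      if (examine_all) examine_all = false;
      else if (num_changed == 0) examine_all = true;
    }
    iterations_ = iter;
    converged_ = iter < max_iter;
    // recompute bias from margin support vectors for stability
    double bsum = 0.0; int bcnt = 0;
    for (int i = 0; i < n_; ++i)
      if (alpha_[i] > 1e-8 && alpha_[i] < C_ - 1e-8) { bsum += y_[i] - F_[i]; ++bcnt; }
    bias_ = bcnt > 0 ? bsum / bcnt : b_;
  }

  const std::vector<double> &alpha() const { return alpha_; }
  const std::vector<double> &F() const { return F_; }
  double bias() const { return bias_; }
  int iterations() const { return iterations_; }
  bool converged() const { return converged_; }

private:
  const double *K_;
  const double *y_;
  double C_, tol_;
  int n_;
  std::vector<double> alpha_, F_;
  double b_, bias_ = 0.0;
  int iterations_ = 0;
  bool converged_ = false;
};

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  SMO solver(REAL(K), REAL(y), (int)y.size(), C, tol);
  solver.solve_core(max_iter);
  const std::vector<double> &a = solver.alpha();
  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = solver.bias(),
                      _["iterations"] = solver.iterations(),
                      _["converged"] = solver.converged());
}

// Mann-Whitney AUC with midranks for ties.
static double rank_auc_cpp(const std::vector<double> &s,
                           const NumericVector &y) {
  const int n = (int)s.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[idx[j + 1]] == s[idx[i]]) ++j;
    double mid = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) rank[idx[k]] = mid;
    i = j + 1;
  }
  double rpos = 0.0; int npos = 0;
  for (int k = 0; k < n; ++k)
    if (y[k] > 0) { rpos += rank[k]; ++npos; }
  int nneg = n - npos;
  if (npos == 0 || nneg == 0) return NA_REAL;
  return (rpos - npos * (npos + 1.0) / 2.0) / ((double)npos * nneg);
}

// Batched candidate evaluation for sequential forward selection: for each
// candidate feature (appended to the already-selected subset) run
// stratified k-fold CV of the Gaussian-kernel SVM and return the pooled
// out-of-fold performance: accuracy (metric 0) or rank AUC (metric 1).
// Per-fold z-scoring uses training-fold mean/sd (sd with n-1 denominator;
// zero sd -> 1), matching the R reference path.
// [[Rcpp::export]]
NumericVector sfs_candidate_objective(NumericMatrix X, NumericVector y,
                                      IntegerVector fold,
                                      IntegerVector selected,
                                      IntegerVector candidates,
                                      double C, double tol, int max_iter,
                                      int metric) {
  const int n = X.nrow();
  const int nsel = selected.size(), ncand = candidates.size();
  int nfold = 0;
  for (int i = 0; i < n; ++i) if (fold[i] > nfold) nfold = fold[i];
  NumericVector out(ncand);
  std::vector<int> tr_idx, te_idx;
  std::vector<double> Ktr, ytr;
  // pooled out-of-fold scores per candidate
  std::vector<std::vector<double>> oof(ncand,
                                       std::vector<double>((size_t)n, 0.0));
  for (int f = 1; f <= nfold; ++f) {
    tr_idx.clear(); te_idx.clear();
    for (int i = 0; i < n; ++i)
      (fold[i] == f ? te_idx : tr_idx).push_back(i);
    const int ntr = (int)tr_idx.size(), nte = (int)te_idx.size();
    if (nte == 0) continue;
    ytr.resize(ntr);
    for (int i = 0; i < ntr; ++i) ytr[i] = y[tr_idx[i]];
    // base squared distances over the selected subset (z-scored per fold)
    std::vector<double> D2tr((size_t)ntr * ntr, 0.0),
        D2te((size_t)nte * ntr, 0.0);
    auto accumulate_feature = [&](int col, std::vector<double> &d2tr,
                                  std::vector<double> &d2te) {
      double mu = 0.0, ss = 0.0;
      for (int i = 0; i < ntr; ++i) mu += X(tr_idx[i], col);
      mu /= ntr;
      for (int i = 0; i < ntr; ++i) {
        double d = X(tr_idx[i], col) - mu; ss += d * d;
      }
      double sdv = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 0.0;
      if (sdv == 0.0) sdv = 1.0;
      std::vector<double> ztr(ntr), zte(nte);
      for (int i = 0; i < ntr; ++i) ztr[i] = (X(tr_idx[i], col) - mu) / sdv;
      for (int i = 0; i < nte; ++i) zte[i] = (X(te_idx[i], col) - mu) / sdv;
      for (int j = 0; j < ntr; ++j)
        for (int i = 0; i < ntr; ++i) {
          double d = ztr[i] - ztr[j];
          d2tr[i + (size_t)ntr * j] += d * d;
        }
      for (int j = 0; j < ntr; ++j)
        for (int i = 0; i < nte; ++i) {
          double d = zte[i] - ztr[j];
          d2te[i + (size_t)nte * j] += d * d;
        }
    };
    for (int s = 0; s < nsel; ++s)
      accumulate_feature(selected[s] - 1, D2tr, D2te);
    for (int c = 0; c < ncand; ++c) {
      std::vector<double> d2tr = D2tr, d2te = D2te;
      accumulate_feature(candidates[c] - 1, d2tr, d2te);
      Ktr.resize((size_t)ntr * ntr);
      for (size_t q = 0; q < d2tr.size(); ++q) Ktr[q] = std::exp(-d2tr[q]);
      SMO solver(Ktr.data(), ytr.data(), ntr, C, tol);
      solver.solve_core(max_iter);
      const std::vector<double> &alpha = solver.alpha();
      for (int i = 0; i < nte; ++i) {
        double sc = solver.bias();
        for (int j = 0; j < ntr; ++j) {
          double a = alpha[j];
          if (a > 1e-12)
            sc += a * ytr[j] * std::exp(-d2te[i + (size_t)nte * j]);
        }
        oof[c][te_idx[i]] = sc;
      }
    }
  }
  for (int c = 0; c < ncand; ++c) {
    if (metric == 1) {
      out[c] = rank_auc_cpp(oof[c], y);
    } else {
      int correct = 0;
      for (int i = 0; i < n; ++i)
        if ((oof[c][i] > 0) == (y[i] > 0)) ++correct;
      out[c] = (double)correct / n;
    }
  }
  return out;
}
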