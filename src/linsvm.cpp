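#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// L1-loss linear SVM trained by dual coordinate descent (the standard
// LIBLINEAR-style solver), with the bias handled as an augmented constant
// feature. Tiny problems only (searchlight neighbourhoods), so a fixed
// iteration cap is ample.
//
// X: n x d training rows (already centred); y: +1/-1; returns w (length d+1,
// last entry the bias weight).
static std::vector<double> svm_train(const std::vector<double>& X, int n,
                                     int d, const std::vector<int>& y,
                                     double C) {
  std::vector<double> w(d + 1, 0.0);
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qd(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // augmented bias feature
    for (int j = 0; j < d; ++j) s += X[i * d + j] * X[i * d + j];
    qd[i] = s;
  }
  const int max_pass = 200;
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[d]; // bias term
      for (int j = 0; j < d; ++j) wx += w[j] * X[i * d + j];
      double g = y[i] * wx - 1.0;
      double a_old = alpha[i];
      double a_new = a_old - g / qd[i];
      if (a_new < 0.0) a_new = 0.0;
      if (a_new > C) a_new = C;
      double delta = a_new - a_old;
      if (delta != 0.0) {
        alpha[i] = a_new;
        double dy = delta * y[i];
        for (int j = 0; j < d; ++j) w[j] += dy * X[i * d + j];
        w[d] += dy;
      }
      if (std::fabs(delta) > max_delta) max_delta = std::fabs(delta);
    }
    if (max_delta < 1e-8) break;
  }
  return w;
}

// Standardize one column on the training rows: centre on the training mean
// and scale by the training SD (unit scale when the SD is zero).
static inline void col_stats(const double* v, int n, double& mu, double& sdv) {
  mu = 0.0;
  for (int i = 0; i < n; ++i) mu += v[i];
  mu /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (v[i] - mu) * (v[i] - mu);
  sdv = (n > 1) ? std::sqrt(ss / (n - 1)) : 0.0;
  if (sdv <= 0.0) sdv = 1.0;
}

// Gather the (samples x neighbourhood) submatrix for a set of voxels,
// standardize columns on the training rows, train, and score the test rows.
// Ties (decision value exactly 0) predict -1, deterministically.
static double fit_score(const NumericMatrix& Xtr, const NumericMatrix& Xte,
                        const std::vector<int>& ytr,
                        const std::vector<int>& yte,
                        const std::vector<int>& vox, double C) {
  int ntr = Xtr.nrow(), nte = Xte.nrow(), d = (int)vox.size();
  std::vector<double> A(ntr * d), B(nte * d), col(ntr);
  for (int j = 0; j < d; ++j) {
    int v = vox[j];
    for (int i = 0; i < ntr; ++i) col[i] = Xtr(i, v);
    double mu, sdv;
    col_stats(col.data(), ntr, mu, sdv);
    for (int i = 0; i < ntr; ++i) A[i * d + j] = (Xtr(i, v) - mu) / sdv;
    for (int i = 0; i < nte; ++i) B[i * d + j] = (Xte(i, v) - mu) / sdv;
  }
  std::vector<double> w = svm_train(A, ntr, d, ytr, C);
  int correct = 0;
  for (int i = 0; i < nte; ++i) {
    double s = w[d];
    for (int j = 0; j < d; ++j) s += w[j] * B[i * d + j];
    int pred = (s > 0.0) ? 1 : -1;
    if (pred == yte[i]) ++correct;
  }
  return (double)correct / nte;
}

// [[Rcpp::export]]
NumericVector cpp_linsvm_predict(NumericMatrix Xtr, IntegerVector ytr,
                                 NumericMatrix Xte, double C = 1.0) {
  int ntr = Xtr.nrow(), d = Xtr.ncol(), nte = Xte.nrow();
  std::vector<double> A(ntr * d), mu(d, 0.0), sdv(d, 1.0), col(ntr);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < ntr; ++i) col[i] = Xtr(i, j);
    col_stats(col.data(), ntr, mu[j], sdv[j]);
    for (int i = 0; i < ntr; ++i) A[i * d + j] = (Xtr(i, j) - mu[j]) / sdv[j];
  }
  std::vector<int> y(ytr.begin(), ytr.end());
  std::vector<double> w = svm_train(A, ntr, d, y, C);
  NumericVector pred(nte);
  for (int i = 0; i < nte; ++i) {
    double s = w[d];
    for (int j = 0; j < d; ++j) s += w[j] * (Xte(i, j) - mu[j]) / sdv[j];
    pred[i] = (s > 0.0) ? 1.0 : -1.0;
  }
  return pred;
}

// Leave-one-run-out searchlight cross-validation.
// X: samples x voxels; y: +1/-1; run: fold id per sample; neigh: list of
// 1-based voxel index vectors per centre voxel.
// [[Rcpp::export]]
NumericVector cpp_searchlight_cv(NumericMatrix X, IntegerVector y,
                                 IntegerVector run, List neigh,
                                 double C = 1.0) {
  int n = X.nrow();
  int n_centre = neigh.size();
  IntegerVector folds = sort_unique(run);
  int n_fold = folds.size();
  NumericVector acc(n_centre);
  for (int c = 0; c < n_centre; ++c) {
    IntegerVector nb = neigh[c];
    std::vector<int> vox(nb.size());
    for (int j = 0; j < nb.size(); ++j) vox[j] = nb[j] - 1;
    double a = 0.0;
    for (int f = 0; f < n_fold; ++f) {
      std::vector<int> tr_rows, te_rows;
      for (int i = 0; i < n; ++i)
        (run[i] == folds[f] ? te_rows : tr_rows).push_back(i);
      int ntr = tr_rows.size(), nte = te_rows.size(), d = vox.size();
      std::vector<double> A(ntr * d), B(nte * d), col(ntr);
      std::vector<int> ytr(ntr), yte(nte);
      for (int i = 0; i < ntr; ++i) ytr[i] = y[tr_rows[i]];
      for (int i = 0; i < nte; ++i) yte[i] = y[te_rows[i]];
      for (int j = 0; j < d; ++j) {
        for (int i = 0; i < ntr; ++i) col[i] = X(tr_rows[i], vox[j]);
        double mu, sdv;
        col_stats(col.data(), ntr, mu, sdv);
        for (int i = 0; i < ntr; ++i)
          A[i * d + j] = (X(tr_rows[i], vox[j]) - mu) / sdv;
        for (int i = 0; i < nte; ++i)
          B[i * d + j] = (X(te_rows[i], vox[j]) - mu) / sdv;
      }
      std::vector<double> w = svm_train(A, ntr, d, ytr, C);
      int correct = 0;
      for (int i = 0; i < nte; ++i) {
        double s = w[d];
        for (int j = 0; j < d; ++j) s += w[j] * B[i * d + j];
        if (((s > 0.0) ? 1 : -1) == yte[i]) ++correct;
      }
      a += (double)correct / nte;
    }
    acc[c] = a / n_fold;
  }
  return acc;
}

// Cross-classification searchlight: train once on Xtr (all original-sound
// runs), test on Xte (one AE class).
// [[Rcpp::export]]
NumericVector cpp_searchlight_cross(NumericMatrix Xtr, IntegerVector ytr,
                                    NumericMatrix Xte, IntegerVector yte,
                                    List neigh, double C = 1.0) {
  int n_centre = neigh.size();
  std::vector<int> ytrv(ytr.begin(), ytr.end());
  std::vector<int> ytev(yte.begin(), yte.end());
  NumericVector acc(n_centre);
  for (int c = 0; c < n_centre; ++c) {
    IntegerVector nb = neigh[c];
    std::vector<int> vox(nb.size());
    for (int j = 0; j < nb.size(); ++j) vox[j] = nb[j] - 1;
    acc[c] = fit_score(Xtr, Xte, ytrv, ytev, vox, C);
  }
  return acc;
}
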