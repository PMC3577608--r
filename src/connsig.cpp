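#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cascade of second-order sections, direct-form II transposed, with explicit
// initial conditions (one zi row per section).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  int n_sec = sos.nrow(), n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < n_sec; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (int t = 0; t < n; ++t) {
      double xt = y[t];
      double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}

// L1-loss (hinge) linear SVM via dual coordinate descent (Hsieh et al. 2008,
// Algorithm 3: random coordinate permutation + active-set shrinking, as in
// LIBLINEAR). The bias is handled by augmenting each sample with a constant
// feature of value 1; the returned vector is c(w, b). Deterministic: the
// coordinate permutation uses a private xorshift generator with a fixed seed,
// so the solution is a pure function of the inputs.
static inline uint32_t xorshift32(uint32_t& s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

static std::vector<double> svm_cd_core(const NumericMatrix& X,
                                       const std::vector<double>& y,
                                       double C, double tol, int max_epochs) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> index(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // augmented bias feature
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
    index[i] = i;
  }
  uint32_t rng = 88172645u;
  int active = n;
  double pg_max_old = R_PosInf, pg_min_old = R_NegInf;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double pg_max_new = R_NegInf, pg_min_new = R_PosInf;
    for (int s = 0; s < active; ++s) {
      int r = s + (int)(xorshift32(rng) % (uint32_t)(active - s));
      std::swap(index[s], index[r]);
    }
    for (int s = 0; s < active; ++s) {
      int i = index[s];
      double xw = w[d];
      for (int j = 0; j < d; ++j) xw += X(i, j) * w[j];
      double g = y[i] * xw - 1.0;
      double pg = 0.0;
      if (alpha[i] == 0.0) {
        if (g > pg_max_old) { // shrink
          std::swap(index[s], index[--active]);
          --s;
          continue;
        }
        if (g < 0.0) pg = g;
      } else if (alpha[i] == C) {
        if (g < pg_min_old) { // shrink
          std::swap(index[s], index[--active]);
          --s;
          continue;
        }
        if (g > 0.0) pg = g;
      } else {
        pg = g;
      }
      if (pg > pg_max_new) pg_max_new = pg;
      if (pg < pg_min_new) pg_min_new = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          w[d] += delta;
        }
      }
    }
    if (pg_max_new - pg_min_new <= tol) {
      if (active == n) break;
      // optimal on the active set: re-activate everything and re-check
      active = n;
      pg_max_old = R_PosInf;
      pg_min_old = R_NegInf;
      continue;
    }
    pg_max_old = (pg_max_new <= 0.0) ? R_PosInf : pg_max_new;
    pg_min_old = (pg_min_new >= 0.0) ? R_NegInf : pg_min_new;
  }
  return w;
}

// [[Rcpp::export]]
NumericVector svm_cd_train(NumericMatrix X, NumericVector y, double C,
                           double tol = 1e-3, int max_epochs = 5000) {
  int n = X.nrow();
  std::vector<double> yy(n);
  for (int i = 0; i < n; ++i) {
    if (y[i] != 1.0 && y[i] != -1.0) stop("labels must be +/-1");
    yy[i] = y[i];
  }
  std::vector<double> w = svm_cd_core(X, yy, C, tol, max_epochs);
  return wrap(w); // length d+1: weights then bias
}

// Full one-against-rest LOOCV over precomputed per-fold PCA projections.
// `folds` is a list of lists with elements Ztr ((n-1) x d_i matrix of
// projected training features, rows in original subject order with the
// held-out subject removed) and zte (projected held-out sample). `labels` are
// integers in 1..k. Returns predicted labels; ties go to the lowest class
// index (the fixed class order).
// [[Rcpp::export]]
IntegerVector ovr_loocv_predict_cpp(List folds, IntegerVector labels, int k,
                                    double C, double tol = 1e-3,
                                    int max_epochs = 5000) {
  int n = folds.size();
  if (labels.size() != n) stop("labels length must match fold count");
  IntegerVector pred(n);
  for (int i = 0; i < n; ++i) {
    List fold = folds[i];
    NumericMatrix Ztr = fold["Ztr"];
    NumericVector zte = fold["zte"];
    int ntr = Ztr.nrow(), d = Ztr.ncol();
    if (ntr != n - 1) stop("fold training size mismatch");
    // training labels = labels with subject i removed
    std::vector<int> ytr(ntr);
    {
      int r = 0;
      for (int s = 0; s < n; ++s) if (s != i) ytr[r++] = labels[s];
    }
    double best = 0.0; int best_c = 0;
    std::vector<double> yy(ntr);
    for (int c = 1; c <= k; ++c) {
      int npos = 0;
      for (int s = 0; s < ntr; ++s) {
        yy[s] = (ytr[s] == c) ? 1.0 : -1.0;
        if (ytr[s] == c) ++npos;
      }
      if (npos == 0) stop("a class is absent from a training fold");
      std::vector<double> w = svm_cd_core(Ztr, yy, C, tol, max_epochs);
      double dec = w[d];
      for (int j = 0; j < d; ++j) dec += w[j] * zte[j];
      if (c == 1 || dec > best) { best = dec; best_c = c; }
    }
    pred[i] = best_c;
  }
  return pred;
}
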