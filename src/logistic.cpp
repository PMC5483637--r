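#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Single-predictor binary logistic regression (intercept + slope), the unit of
// work inside the bootstrap / LOOCV / permutation loops. Complete separation is
// detected up front and replaced by the deterministic midpoint-threshold rule:
// the accuracy statistic only depends on the decision boundary, so the
// unbounded MLE is never needed.

struct Fit1D {
  double a, b;        // intercept, slope (NA when separated)
  double boundary;    // midpoint decision boundary when separated
  int sep;            // complete separation flag
  int dir;            // +1: positive class above boundary, -1: below
};

static Fit1D fit1d(const double* x, const int* y, int n) {
  Fit1D f;
  f.a = NA_REAL; f.b = NA_REAL; f.boundary = 0.0; f.sep = 0; f.dir = 0;

  double min1 = R_PosInf, max1 = R_NegInf, min0 = R_PosInf, max0 = R_NegInf;
  int n1 = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] == 1) {
      ++n1;
      if (x[i] < min1) min1 = x[i];
      if (x[i] > max1) max1 = x[i];
    } else {
      if (x[i] < min0) min0 = x[i];
      if (x[i] > max0) max0 = x[i];
    }
  }
  int n0 = n - n1;
  if (n1 == 0 || n0 == 0) stop("both classes must be present");

  double xmin = std::min(min0, min1), xmax = std::max(max0, max1);
  if (xmax - xmin <= 0.0) {           // constant predictor: intercept-only MLE
    double p = (double)n1 / (double)n;
    f.a = std::log(p / (1.0 - p));
    f.b = 0.0;
    return f;
  }
  if (min1 > max0) {                  // complete separation, MS above
    f.sep = 1; f.dir = 1; f.boundary = 0.5 * (min1 + max0);
    return f;
  }
  if (max1 < min0) {                  // complete separation, MS below
    f.sep = 1; f.dir = -1; f.boundary = 0.5 * (max1 + min0);
    return f;
  }

  // Newton-Raphson on standardised x for conditioning.
  double mx = 0.0, sx = 0.0;
  for (int i = 0; i < n; ++i) mx += x[i];
  mx /= n;
  for (int i = 0; i < n; ++i) sx += (x[i] - mx) * (x[i] - mx);
  sx = std::sqrt(sx / (n - 1));

  double a = 0.0, b = 0.0;
  for (int it = 0; it < 100; ++it) {
    double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
    for (int i = 0; i < n; ++i) {
      double z = (x[i] - mx) / sx;
      double eta = a + b * z;
      double p = 1.0 / (1.0 + std::exp(-eta));
      double w = p * (1.0 - p);
      double r = y[i] - p;
      g0 += r; g1 += r * z;
      h00 += w; h01 += w * z; h11 += w * z * z;
    }
    double det = h00 * h11 - h01 * h01;
    if (det < 1e-300) break;
    double da = (h11 * g0 - h01 * g1) / det;
    double db = (-h01 * g0 + h00 * g1) / det;
    a += da; b += db;
    if (std::fabs(da) + std::fabs(db) < 1e-12) break;
  }
  f.a = a - b * mx / sx;
  f.b = b / sx;
  return f;
}

// P(MS) >= 0.5 predicts MS; ties at the boundary go to the positive class.
static inline int predict1(const Fit1D& f, double x) {
  if (f.sep) return (f.dir * (x - f.boundary) >= 0.0) ? 1 : 0;
  return (f.a + f.b * x >= 0.0) ? 1 : 0;
}

static double accuracy(const Fit1D& f, const double* x, const int* y, int n) {
  int ok = 0;
  for (int i = 0; i < n; ++i) ok += (predict1(f, x[i]) == y[i]);
  return (double)ok / (double)n;
}

static double loocv(const double* x, const int* y, int n) {
  std::vector<double> xt(n - 1);
  std::vector<int> yt(n - 1);
  int ok = 0;
  for (int i = 0; i < n; ++i) {
    int m = 0, n1 = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      xt[m] = x[j]; yt[m] = y[j];
      n1 += y[j];
      ++m;
    }
    int pred;
    if (n1 == 0) pred = 0;                 // single-class fold: predict it
    else if (n1 == m) pred = 1;
    else {
      Fit1D f = fit1d(xt.data(), yt.data(), m);
      pred = predict1(f, x[i]);
    }
    ok += (pred == y[i]);
  }
  return (double)ok / (double)n;
}

// [[Rcpp::export]]
NumericVector cpp_fit_logistic(NumericVector x, IntegerVector y) {
  Fit1D f = fit1d(x.begin(), y.begin(), x.size());
  return NumericVector::create(
    _["intercept"] = f.a, _["slope"] = f.b, _["separated"] = (double)f.sep,
    _["boundary"] = f.boundary, _["direction"] = (double)f.dir);
}

// [[Rcpp::export]]
double cpp_within_accuracy(NumericVector x, IntegerVector y) {
  Fit1D f = fit1d(x.begin(), y.begin(), x.size());
  return accuracy(f, x.begin(), y.begin(), x.size());
}

// [[Rcpp::export]]
IntegerVector cpp_predict(NumericVector x, IntegerVector y, NumericVector newx) {
  Fit1D f = fit1d(x.begin(), y.begin(), x.size());
  IntegerVector out(newx.size());
  for (int i = 0; i < newx.size(); ++i) out[i] = predict1(f, newx[i]);
  return out;
}

// [[Rcpp::export]]
double cpp_loocv(NumericVector x, IntegerVector y) {
  return loocv(x.begin(), y.begin(), x.size());
}

// LOOCV accuracy for each column of permuted labels.
// [[Rcpp::export]]
NumericVector cpp_loocv_many(NumericVector x, IntegerMatrix ymat) {
  int n = x.size(), K = ymat.ncol();
  if (ymat.nrow() != n) stop("label matrix does not match x");
  NumericVector out(K);
  std::vector<int> y(n);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) y[i] = ymat(i, k);
    out[k] = loocv(x.begin(), y.data(), n);
  }
  return out;
}

// Refit-and-score training accuracy for each column of resample indices
// (1-based rows of the original data).
// [[Rcpp::export]]
NumericVector cpp_boot_accuracy(NumericVector x, IntegerVector y, IntegerMatrix idx) {
  int n = idx.nrow(), B = idx.ncol();
  NumericVector out(B);
  std::vector<double> xb(n);
  std::vector<int> yb(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = idx(i, b) - 1;
      xb[i] = x[j]; yb[i] = y[j];
    }
    Fit1D f = fit1d(xb.data(), yb.data(), n);
    out[b] = accuracy(f, xb.data(), yb.data(), n);
  }
  return out;
}
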