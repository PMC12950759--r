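// Hot elementwise kernels for the neural layers. Fusing the activation
// value and its derivative into one pass, and doing row-vector broadcasts
// in C, removes the dominant interpreter overhead from training loops;
// matrix products stay in R/BLAS.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GELU_C = 0.7978845608028654; // sqrt(2/pi)

// value and derivative of tanh-approximation GELU in one pass
// [[Rcpp::export]]
List gelu_both_cpp(NumericMatrix x) {
  R_xlen_t n = x.size();
  NumericMatrix y(x.nrow(), x.ncol()), g(x.nrow(), x.ncol());
  const double *px = x.begin();
  double *py = y.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = px[i];
    double inner = GELU_C * (v + 0.044715 * v * v * v);
    double th = std::tanh(inner);
    py[i] = 0.5 * v * (1.0 + th);
    pg[i] = 0.5 * (1.0 + th) +
            0.5 * v * (1.0 - th * th) * GELU_C * (1.0 + 3.0 * 0.044715 * v * v);
  }
  return List::create(_["y"] = y, _["g"] = g);
}

// [[Rcpp::export]]
List elu_both_cpp(NumericMatrix x) {
  R_xlen_t n = x.size();
  NumericMatrix y(x.nrow(), x.ncol()), g(x.nrow(), x.ncol());
  const double *px = x.begin();
  double *py = y.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = px[i];
    if (v > 0) { py[i] = v; pg[i] = 1.0; }
    else { double e = std::exp(v); py[i] = e - 1.0; pg[i] = e; }
  }
  return List::create(_["y"] = y, _["g"] = g);
}

// [[Rcpp::export]]
List relu_both_cpp(NumericMatrix x) {
  R_xlen_t n = x.size();
  NumericMatrix y(x.nrow(), x.ncol()), g(x.nrow(), x.ncol());
  const double *px = x.begin();
  double *py = y.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = px[i];
    py[i] = v > 0 ? v : 0.0;
    pg[i] = v > 0 ? 1.0 : 0.0;
  }
  return List::create(_["y"] = y, _["g"] = g);
}

// numerically stable softmax over rows; column-major passes for locality
// [[Rcpp::export]]
NumericMatrix softmax_rows_cpp(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix y(nr, nc);
  std::vector<double> m(nr, R_NegInf), s(nr, 0.0);
  const double *px = x.begin();
  double *py = y.begin();
  for (int j = 0; j < nc; ++j) {
    const double *col = px + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) if (col[i] > m[i]) m[i] = col[i];
  }
  for (int j = 0; j < nc; ++j) {
    const double *col = px + (R_xlen_t)j * nr;
    double *ycol = py + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) { double e = std::exp(col[i] - m[i]); ycol[i] = e; s[i] += e; }
  }
  for (int i = 0; i < nr; ++i) s[i] = 1.0 / s[i];
  for (int j = 0; j < nc; ++j) {
    double *ycol = py + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) ycol[i] *= s[i];
  }
  return y;
}

// backward of row softmax: dS = A * (dA - rowSums(dA * A))
// [[Rcpp::export]]
NumericMatrix softmax_backward_cpp(NumericMatrix A, NumericMatrix dA) {
  int nr = A.nrow(), nc = A.ncol();
  NumericMatrix dS(nr, nc);
  std::vector<double> rs(nr, 0.0);
  const double *pa = A.begin(), *pd = dA.begin();
  double *po = dS.begin();
  for (int j = 0; j < nc; ++j) {
    const double *ac = pa + (R_xlen_t)j * nr;
    const double *dc = pd + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) rs[i] += ac[i] * dc[i];
  }
  for (int j = 0; j < nc; ++j) {
    const double *ac = pa + (R_xlen_t)j * nr;
    const double *dc = pd + (R_xlen_t)j * nr;
    double *oc = po + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) oc[i] = ac[i] * (dc[i] - rs[i]);
  }
  return dS;
}

// x + v broadcast over rows (v indexed by column)
// [[Rcpp::export]]
NumericMatrix add_row_vec_cpp(NumericMatrix x, NumericVector v) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix y(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double b = v[j];
    const double *px = &x(0, j);
    double *py = &y(0, j);
    for (int i = 0; i < nr; ++i) py[i] = px[i] + b;
  }
  return y;
}

// x * v broadcast over rows (v indexed by column)
// [[Rcpp::export]]
NumericMatrix mul_row_vec_cpp(NumericMatrix x, NumericVector v) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix y(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double b = v[j];
    const double *px = &x(0, j);
    double *py = &y(0, j);
    for (int i = 0; i < nr; ++i) py[i] = px[i] * b;
  }
  return y;
}
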