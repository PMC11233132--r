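#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for one lasso target column, operating on the
// Gram matrix: minimizes 0.5*||y - X w||^2 + lam*||w||_1 given XtX and Xty.
// Convergence is a per-coordinate KKT check:
//   grad_j = (XtX w)_j - Xty_j
//   active   w_j != 0: |grad_j + lam*sign(w_j)| <= tol
//   inactive w_j == 0: |grad_j| <= lam + tol
// The gradient is updated incrementally and refreshed exactly at regular
// intervals (and before declaring convergence) to stop floating-point
// drift from masking or faking convergence. Between full sweeps the
// active set (nonzero coordinates) is iterated alone, glmnet-style.

static void refresh_grad(const NumericMatrix& XtX, const NumericVector& Xty,
                         const NumericVector& w, NumericVector& grad) {
  const int P = XtX.nrow();
  for (int j = 0; j < P; ++j) {
    double acc = -Xty[j];
    for (int k = 0; k < P; ++k) acc += XtX(j, k) * w[k];
    grad[j] = acc;
  }
}

static double kkt_worst(const NumericVector& w, const NumericVector& grad,
                        double lam) {
  double worst = 0.0;
  for (int j = 0; j < w.size(); ++j) {
    double v = (w[j] != 0.0)
      ? std::abs(grad[j] + lam * (w[j] > 0 ? 1.0 : -1.0))
      : std::max(std::abs(grad[j]) - lam, 0.0);
    if (v > worst) worst = v;
  }
  return worst;
}

// one coordinate-descent pass over the coordinates listed in idx
static void cd_pass(const NumericMatrix& XtX, double lam,
                    const std::vector<int>& idx,
                    NumericVector& w, NumericVector& grad) {
  const int P = XtX.nrow();
  for (size_t t = 0; t < idx.size(); ++t) {
    const int j = idx[t];
    const double d = XtX(j, j);
    if (d == 0.0) continue;  // zero column: coefficient stays 0
    const double rho = -grad[j] + d * w[j];
    double wj_new;
    if (rho > lam) wj_new = (rho - lam) / d;
    else if (rho < -lam) wj_new = (rho + lam) / d;
    else wj_new = 0.0;
    const double delta = wj_new - w[j];
    if (delta != 0.0) {
      for (int k = 0; k < P; ++k) grad[k] += XtX(k, j) * delta;
      w[j] = wj_new;
    }
  }
}

// [[Rcpp::export(name = ".lasso_cd_column")]]
List lasso_cd_column(const NumericMatrix& XtX, const NumericVector& Xty,
                     double lam, double tol, int max_iter,
                     Nullable<NumericVector> w_start = R_NilValue) {
  const int P = XtX.nrow();
  NumericVector w(P);
  if (w_start.isNotNull()) w = clone(NumericVector(w_start));
  NumericVector grad(P);
  refresh_grad(XtX, Xty, w, grad);

  std::vector<int> all_idx(P);
  for (int j = 0; j < P; ++j) all_idx[j] = j;

  double worst = R_PosInf;
  bool converged = false;
  int iter = 0;
  const int refresh_every = 64;
  while (iter < max_iter) {
    // full sweep
    cd_pass(XtX, lam, all_idx, w, grad);
    ++iter;
    if (iter % refresh_every == 0) refresh_grad(XtX, Xty, w, grad);
    worst = kkt_worst(w, grad, lam);
    if (worst <= tol) {
      refresh_grad(XtX, Xty, w, grad);
      worst = kkt_worst(w, grad, lam);
      if (worst <= tol) { converged = true; break; }
    }
    // active-set passes until stable there
    std::vector<int> act;
    for (int j = 0; j < P; ++j) if (w[j] != 0.0) act.push_back(j);
    int inner = 0;
    while (!act.empty() && iter < max_iter && inner < refresh_every) {
      cd_pass(XtX, lam, act, w, grad);
      ++iter; ++inner;
      double w_act = 0.0;
      for (size_t t = 0; t < act.size(); ++t) {
        const int j = act[t];
        double v = (w[j] != 0.0)
          ? std::abs(grad[j] + lam * (w[j] > 0 ? 1.0 : -1.0))
          : std::max(std::abs(grad[j]) - lam, 0.0);
        if (v > w_act) w_act = v;
      }
      if (w_act <= 0.5 * tol) break;
    }
    refresh_grad(XtX, Xty, w, grad);
  }
  return List::create(_["w"] = w, _["converged"] = converged,
                      _["iters"] = iter, _["worst_kkt"] = worst);
}
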