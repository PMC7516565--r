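#include <Rcpp.h>
using namespace Rcpp;

// Penalized weighted-least-squares coordinate descent for
//   R_n(b) + lambda * ||b_tilde||_1    (intercept unpenalized).
//
// Outer loop: quadratic approximation of the loss at the current linear
// predictor via working weights and a working residual (IRLS):
//   logistic  w = mu(1-mu) (Newton; clamped),   r = (y - mu) / w
//   quadratic w = 1 (exact),                    r = y - eta
//   huber     w = 1 or delta/|res| (a true
//             majorizer of the Huber function), r = y - eta
// Inner loop: cyclic coordinate descent with active-set sweeps on the
// weighted least-squares subproblem.  A step-halving safeguard keeps the
// penalized objective monotone (the Newton approximation for the
// logistic loss is not an upper bound).  Convergence is declared on the
// sup-norm KKT residual of the original problem.
// loss_code: 1 logistic, 2 quadratic, 3 huber.

static inline double loss_deriv1(double eta, double y, int loss_code,
                                 double delta) {
  switch (loss_code) {
  case 1: return 1.0 / (1.0 + std::exp(-eta)) - y;
  case 2: return eta - y;
  default: {
    double r = y - eta;
    if (r > delta) r = delta;
    else if (r < -delta) r = -delta;
    return -r;
  }
  }
}

static inline double loss_val1(double eta, double y, int loss_code,
                               double delta) {
  switch (loss_code) {
  case 1: {
    double m = eta > 0 ? eta : 0.0;
    return m - y * eta + std::log1p(std::exp(-std::fabs(eta)));
  }
  case 2: {
    double r = y - eta;
    return 0.5 * r * r;
  }
  default: {
    double r = std::fabs(y - eta);
    return r <= delta ? 0.5 * r * r : delta * (r - 0.5 * delta);
  }
  }
}

// [[Rcpp::export(name = ".cd_lasso_fit")]]
List cd_lasso_fit(NumericMatrix X, NumericVector y, int loss_code,
                  double delta, double lambda, double b0_init,
                  NumericVector bt_init, double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  const double* x = &X[0];
  const double* yy = &y[0];
  double b0 = b0_init;
  NumericVector bt = clone(bt_init);
  double* b = &bt[0];
  std::vector<double> eta(n), g(n), r(n), w(n), wxsq(p);
  std::vector<double> b_prev(p);

  auto recompute_eta = [&]() {
    for (int i = 0; i < n; ++i) eta[i] = b0;
    for (int j = 0; j < p; ++j) {
      if (b[j] != 0.0) {
        const double bj = b[j];
        const double* xj = x + (size_t)j * n;
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
      }
    }
  };
  auto objective = [&]() {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += loss_val1(eta[i], yy[i], loss_code, delta);
    s /= n;
    double l1 = 0.0;
    for (int j = 0; j < p; ++j) l1 += std::fabs(b[j]);
    return s + lambda * l1;
  };

  recompute_eta();
  double obj = objective();
  int sweeps = 0;
  bool converged = false;
  double kkt = R_PosInf;

  while (true) {
    // KKT residual of the original problem
    double g0 = 0.0;
    for (int i = 0; i < n; ++i) {
      g[i] = loss_deriv1(eta[i], yy[i], loss_code, delta);
      g0 += g[i];
    }
    g0 /= n;
    kkt = std::fabs(g0);
    for (int j = 0; j < p; ++j) {
      const double* xj = x + (size_t)j * n;
      double gj = 0.0;
      for (int i = 0; i < n; ++i) gj += xj[i] * g[i];
      gj /= n;
      double res;
      if (b[j] != 0.0)
        res = std::fabs(gj + lambda * (b[j] > 0 ? 1.0 : -1.0));
      else {
        res = std::fabs(gj) - lambda;
        if (res < 0.0) res = 0.0;
      }
      if (res > kkt) kkt = res;
    }
    if (kkt <= tol) { converged = true; break; }
    if (sweeps >= max_sweeps) break;

    // working weights and residual
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      double wi, ri;
      if (loss_code == 1) {
        double mu = 1.0 / (1.0 + std::exp(-eta[i]));
        wi = mu * (1.0 - mu);
        if (wi < 1e-6) wi = 1e-6;
        ri = (yy[i] - mu) / wi;
      } else if (loss_code == 2) {
        wi = 1.0;
        ri = yy[i] - eta[i];
      } else {
        double res = yy[i] - eta[i];
        double ares = std::fabs(res);
        wi = (ares <= delta || ares == 0.0) ? 1.0 : delta / ares;
        ri = res;
      }
      w[i] = wi; r[i] = ri; wsum += wi;
    }
    for (int j = 0; j < p; ++j) {
      const double* xj = x + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
      wxsq[j] = s / n;
    }
    double b0_prev = b0;
    for (int j = 0; j < p; ++j) b_prev[j] = b[j];

    // inner coordinate descent on the weighted LS subproblem
    int inner = 0;
    while (true) {
      double maxd = 0.0;
      double d0 = 0.0;
      for (int i = 0; i < n; ++i) d0 += w[i] * r[i];
      d0 /= wsum;
      if (d0 != 0.0) {
        b0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
        maxd = std::fabs(d0);
      }
      for (int j = 0; j < p; ++j) {
        if (wxsq[j] <= 1e-12) continue;
        if (inner > 0 && b[j] == 0.0) continue;   // active-set sweep
        const double* xj = x + (size_t)j * n;
        double gj = 0.0;
        for (int i = 0; i < n; ++i) gj += w[i] * xj[i] * r[i];
        gj = gj / n + wxsq[j] * b[j];
        double bj = 0.0;
        if (gj > lambda) bj = (gj - lambda) / wxsq[j];
        else if (gj < -lambda) bj = (gj + lambda) / wxsq[j];
        double dj = bj - b[j];
        if (dj != 0.0) {
          b[j] = bj;
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * dj;
          double d = std::fabs(dj) * std::sqrt(wxsq[j]);
          if (d > maxd) maxd = d;
        }
      }
      ++inner; ++sweeps;
      if (maxd < 1e-10 || inner >= 100 || sweeps >= max_sweeps) break;
    }

    recompute_eta();
    double new_obj = objective();
    // step-halving safeguard toward the previous iterate
    int halvings = 0;
    while (new_obj > obj + 1e-12 && halvings < 20) {
      b0 = 0.5 * (b0 + b0_prev);
      for (int j = 0; j < p; ++j) b[j] = 0.5 * (b[j] + b_prev[j]);
      recompute_eta();
      new_obj = objective();
      ++halvings;
    }
    if (new_obj > obj + 1e-12) {
      // no progress even after halving: accept the previous iterate
      b0 = b0_prev;
      for (int j = 0; j < p; ++j) b[j] = b_prev[j];
      recompute_eta();
      break;
    }
    obj = new_obj;
  }

  return List::create(_["intercept"] = b0, _["beta"] = bt,
                      _["kkt"] = kkt, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
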