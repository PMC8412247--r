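#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Poisson kernel on the circle, normalized to integrate to 1 over [0, 2pi):
//   P_r(phi) = (1 - r^2) / (2 pi (1 - 2 r cos phi + r^2)),  0 < r < 1.
// p1, p2 are first and second derivatives w.r.t. phi.
static inline void pkern(double phi, double r, double amp,
                         double &p0, double &p1, double &p2) {
  double c = std::cos(phi), s = std::sin(phi);
  double D  = 1.0 - 2.0 * r * c + r * r;
  double D1 = 2.0 * r * s;
  double D2 = 2.0 * r * c;
  double iD = 1.0 / D;
  p0 = amp * iD;
  p1 = -amp * D1 * iD * iD;
  p2 = -amp * (D2 * D - 2.0 * D1 * D1) * iD * iD * iD;
}

// [[Rcpp::export]]
NumericMatrix cpp_poisson_gram(NumericVector a, NumericVector b, double r) {
  int n = a.size(), m = b.size();
  double amp = (1.0 - r * r) / (2.0 * M_PI);
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double p0, p1, p2;
      pkern(a[i] - b[j], r, amp, p0, p1, p2);
      K(i, j) = p0;
    }
  return K;
}

// Evaluate x(t) = sum_m wx_m P(sup_m - t) (and y) with derivatives up to
// `order` (0, 1 or 2) w.r.t. t. Columns: x, y[, dx, dy[, ddx, ddy]].
// d/dt P(sup - t) = -P'(sup - t); d2/dt2 P(sup - t) = P''(sup - t).
// [[Rcpp::export]]
NumericMatrix cpp_eval_contour(NumericVector support, NumericVector wx,
                               NumericVector wy, double r,
                               NumericVector theta, int order) {
  int n = theta.size(), M = support.size();
  double amp = (1.0 - r * r) / (2.0 * M_PI);
  NumericMatrix out(n, 2 * (order + 1));
  for (int i = 0; i < n; ++i) {
    double x = 0, y = 0, dx = 0, dy = 0, ddx = 0, ddy = 0;
    for (int m = 0; m < M; ++m) {
      double p0, p1, p2;
      pkern(support[m] - theta[i], r, amp, p0, p1, p2);
      x += wx[m] * p0;  y += wy[m] * p0;
      if (order >= 1) { dx -= wx[m] * p1; dy -= wy[m] * p1; }
      if (order >= 2) { ddx += wx[m] * p2; ddy += wy[m] * p2; }
    }
    out(i, 0) = x; out(i, 1) = y;
    if (order >= 1) { out(i, 2) = dx; out(i, 3) = dy; }
    if (order >= 2) { out(i, 4) = ddx; out(i, 5) = ddy; }
  }
  return out;
}

struct FlowObjective {
  const NumericVector &sx, &sy, &support, &wx, &wy;
  double cx, cy, r, lambda, dt;
  int N;
  FlowObjective(const NumericVector &sx_, const NumericVector &sy_,
                const NumericVector &sup_, const NumericVector &wx_,
                const NumericVector &wy_, double cx_, double cy_, double r_,
                double lambda_, double dt_)
      : sx(sx_), sy(sy_), support(sup_), wx(wx_), wy(wy_), cx(cx_), cy(cy_),
        r(r_), lambda(lambda_), dt(dt_), N(sx_.size()) {}

  // H = F + lambda U on the lifted angles phi; fills grad if not NULL.
  double eval(const std::vector<double> &phi, std::vector<double> *grad,
              double *Fout, double *Uout) const {
    int M = support.size();
    double amp = (1.0 - r * r) / (2.0 * M_PI);
    double F = 0.0;
    std::vector<double> X(N), Y(N), dX(N), dY(N);
    for (int i = 0; i < N; ++i) {
      double x = 0, y = 0, dx = 0, dy = 0;
      for (int m = 0; m < M; ++m) {
        double p0, p1, p2;
        pkern(support[m] - phi[i], r, amp, p0, p1, p2);
        x += wx[m] * p0; y += wy[m] * p0;
        dx -= wx[m] * p1; dy -= wy[m] * p1;
      }
      X[i] = x + cx; Y[i] = y + cy; dX[i] = dx; dY[i] = dy;
      double ex = X[i] - sx[i], ey = Y[i] - sy[i];
      F += ex * ex + ey * ey;
    }
    F /= (double)N * dt * dt;
    double U = 0.0;
    for (int i = 0; i < N; ++i) {
      double g = (i + 1 < N ? phi[i + 1] - phi[i]
                            : phi[0] + 2.0 * M_PI - phi[N - 1]);
      U += g * g;
    }
    U *= (double)N;
    if (grad) {
      for (int i = 0; i < N; ++i) {
        double ex = X[i] - sx[i], ey = Y[i] - sy[i];
        double gF = 2.0 / ((double)N * dt * dt) * (ex * dX[i] + ey * dY[i]);
        double gprev = (i > 0 ? phi[i] - phi[i - 1]
                              : phi[0] + 2.0 * M_PI - phi[N - 1]);
        double gnext = (i + 1 < N ? phi[i + 1] - phi[i]
                                  : phi[0] + 2.0 * M_PI - phi[N - 1]);
        double gU = 2.0 * (double)N * (gprev - gnext);
        (*grad)[i] = gF + lambda * gU;
      }
    }
    if (Fout) *Fout = F;
    if (Uout) *Uout = U;
    return F + lambda * U;
  }
};

// Gradient descent (Barzilai-Borwein step with Armijo backtracking) for the
// discrete flow objective H = F + lambda U over lifted target angles.
// [[Rcpp::export]]
List cpp_flow_descent(NumericVector source_x, NumericVector source_y,
                      NumericVector support, NumericVector wx,
                      NumericVector wy, double cx, double cy, double r,
                      NumericVector theta_init, double lambda, double dt,
                      double tol, int maxit, double step0) {
  int N = theta_init.size();
  FlowObjective obj(source_x, source_y, support, wx, wy, cx, cy, r, lambda, dt);
  std::vector<double> phi(theta_init.begin(), theta_init.end());
  std::vector<double> grad(N), grad_old(N), phi_old(N), trial(N);
  double F, U;
  double H = obj.eval(phi, &grad, &F, &U);
  double step = step0;
  int it = 0;
  bool converged = false;
  double gmax = 0.0;
  for (it = 0; it < maxit; ++it) {
    gmax = 0.0;
    double gnorm2 = 0.0;
    for (int i = 0; i < N; ++i) {
      gnorm2 += grad[i] * grad[i];
      double a = std::fabs(grad[i]);
      if (a > gmax) gmax = a;
    }
    if (gmax < tol) { converged = true; break; }
    if (it > 0) {
      // BB1 step: (s.s)/(s.y)
      double ss = 0.0, sy = 0.0;
      for (int i = 0; i < N; ++i) {
        double s = phi[i] - phi_old[i], y = grad[i] - grad_old[i];
        ss += s * s; sy += s * y;
      }
      if (sy > 1e-300) step = ss / sy;
      else step = step0;
      if (step < 1e-15) step = 1e-15;
      if (step > 1e6) step = 1e6;
    }
    phi_old = phi; grad_old = grad;
    double t = step;
    double Hnew = H;
    bool ok = false;
    for (int bt = 0; bt < 60; ++bt) {
      for (int i = 0; i < N; ++i) trial[i] = phi_old[i] - t * grad_old[i];
      Hnew = obj.eval(trial, NULL, NULL, NULL);
      if (Hnew <= H - 1e-4 * t * gnorm2) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) break;  // no acceptable decrease: stalled at best iterate
    phi = trial;
    double Hprev = H;
    H = obj.eval(phi, &grad, &F, &U);
    if (Hprev - H <= 1e-15 * (std::fabs(Hprev) + 1e-300) && it > 2) break;
  }
  H = obj.eval(phi, &grad, &F, &U);
  return List::create(_["theta"] = NumericVector(phi.begin(), phi.end()),
                      _["F"] = F, _["U"] = U, _["H"] = H,
                      _["iterations"] = it, _["converged"] = converged,
                      _["grad_max"] = gmax);
}

// 8-connected component labeling on a logical grid; columns (marker axis)
// optionally periodic, rows (time axis) never. Returns 0 for background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, bool periodic_cols) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next_label = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next_label;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= nr) continue;
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int cc = c + dc;
            if (periodic_cols) cc = (cc + nc) % nc;
            else if (cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next_label;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
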