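#include <Rcpp.h>
using namespace Rcpp;

// Two-process (fast/slow) state-space recursion over a perturbation schedule.
// Closed-loop: the error driving learning is the perturbation minus the
// model's own output on the previous trial. Open-loop ("observed") mode uses
// the measured gain deviation of the previous trial instead, falling back to
// the model output where the measurement is missing (rejected trial).
// Columns of the result: error, state_fast, state_slow, adaptation.
// [[Rcpp::export]]
NumericMatrix cpp_dual_state(NumericVector p,
                             double alpha_fast, double beta_fast,
                             double alpha_slow, double beta_slow,
                             double gamma_fast, double gamma_slow,
                             bool closed_loop,
                             NumericVector observed_dev) {
  int n = p.size();
  NumericMatrix out(n, 4);
  bool have_obs = (observed_dev.size() == (R_xlen_t)n);
  double xf = 0.0, xs = 0.0;
  double prev_src = 0.0;  // output (or observation) of trial i-1
  for (int i = 0; i < n; ++i) {
    double eps = p[i] - prev_src;
    xf = alpha_fast * eps + beta_fast * xf;
    xs = alpha_slow * eps + beta_slow * xs;
    double adapt = gamma_fast * xf + gamma_slow * xs;
    out(i, 0) = eps;
    out(i, 1) = xf;
    out(i, 2) = xs;
    out(i, 3) = adapt;
    if (!closed_loop && have_obs && !NumericVector::is_na(observed_dev[i]))
      prev_src = observed_dev[i];
    else
      prev_src = adapt;
  }
  return out;
}

// Sum of squared residuals between observed gain deviations and the model
// output, skipping missing observations; the recursion advances on every
// trial regardless of validity.
// [[Rcpp::export]]
double cpp_dual_state_sse(NumericVector p, NumericVector ydev,
                          double alpha_fast, double beta_fast,
                          double alpha_slow, double beta_slow,
                          double gamma_fast, double gamma_slow,
                          bool closed_loop) {
  int n = p.size();
  double xf = 0.0, xs = 0.0, prev_src = 0.0, sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double eps = p[i] - prev_src;
    xf = alpha_fast * eps + beta_fast * xf;
    xs = alpha_slow * eps + beta_slow * xs;
    double adapt = gamma_fast * xf + gamma_slow * xs;
    if (!NumericVector::is_na(ydev[i])) {
      double r = ydev[i] - adapt;
      sse += r * r;
    }
    if (!closed_loop && !NumericVector::is_na(ydev[i]))
      prev_src = ydev[i];
    else
      prev_src = adapt;
  }
  return sse;
}

// ---- exponential timescale fit -------------------------------------------
// Model (form 0, the default): fit(t) = 1 - alpha * (1 - exp(-t/beta)),
// starting at 1 and approaching 1 - alpha. Form 1 is the algebraic variant
// (1 - alpha) * (exp(-t/beta) - 1) + 1 which approaches alpha instead.
// Both are linear in alpha given beta, so alpha is profiled out and beta is
// found by a log-spaced grid scan refined with golden-section search.

static double profiled_sse(const std::vector<double>& t,
                           const std::vector<double>& y,
                           double beta, int form, double* alpha_out) {
  size_t n = t.size();
  double sgg = 0.0, sgd = 0.0;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) {
    g[i] = 1.0 - std::exp(-t[i] / beta);
    double d = (form == 0) ? (1.0 - y[i]) : (y[i] - 1.0 + g[i]);
    sgg += g[i] * g[i];
    sgd += g[i] * d;
  }
  double a = (sgg > 0.0) ? sgd / sgg : 0.0;
  double sse = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double fit = (form == 0) ? (1.0 - a * g[i]) : (1.0 - g[i] + a * g[i]);
    double r = y[i] - fit;
    sse += r * r;
  }
  if (alpha_out) *alpha_out = a;
  return sse;
}

// [[Rcpp::export]]
List cpp_fit_exp(NumericVector t_in, NumericVector y_in,
                 double beta_min, double beta_max, int form, int ngrid) {
  std::vector<double> t, y;
  t.reserve(t_in.size());
  y.reserve(y_in.size());
  for (R_xlen_t i = 0; i < t_in.size(); ++i) {
    if (R_finite(t_in[i]) && R_finite(y_in[i])) {
      t.push_back(t_in[i]);
      y.push_back(y_in[i]);
    }
  }
  int n = (int)t.size();
  if (n < 2) stop("need at least 2 finite points");

  double ymean = 0.0;
  for (int i = 0; i < n; ++i) ymean += y[i];
  ymean /= n;
  double yvar = 0.0;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ymean) * (y[i] - ymean);
  bool degenerate = yvar < 1e-20;

  double lmin = std::log(beta_min), lmax = std::log(beta_max);
  int best = 0;
  double best_sse = R_PosInf;
  std::vector<double> grid(ngrid);
  for (int k = 0; k < ngrid; ++k) {
    grid[k] = std::exp(lmin + (lmax - lmin) * k / (ngrid - 1));
    double s = profiled_sse(t, y, grid[k], form, nullptr);
    if (s < best_sse) { best_sse = s; best = k; }
  }
  bool edge = (best == 0 || best == ngrid - 1);

  // golden-section refinement on log(beta) around the best grid point
  double lo = std::log(grid[best > 0 ? best - 1 : 0]);
  double hi = std::log(grid[best < ngrid - 1 ? best + 1 : ngrid - 1]);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = profiled_sse(t, y, std::exp(c), form, nullptr);
  double fd = profiled_sse(t, y, std::exp(d), form, nullptr);
  for (int it = 0; it < 200 && (b - a) > 1e-12; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = profiled_sse(t, y, std::exp(c), form, nullptr);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = profiled_sse(t, y, std::exp(d), form, nullptr);
    }
  }
  double beta = std::exp(0.5 * (a + b));
  if (beta > beta_max) beta = beta_max;
  double alpha;
  double sse = profiled_sse(t, y, beta, form, &alpha);

  return List::create(_["alpha"] = alpha, _["beta"] = beta, _["sse"] = sse,
                      _["n"] = n, _["edge"] = edge,
                      _["degenerate"] = degenerate);
}

// One bootstrap fold: average the resampled participants' series per
// condition and fit the exponential to each average. `cond_mats` holds one
// participants x trials matrix per condition (NA = rejected trial); `idx` is
// the fold x participant resample matrix (1-based), shared across conditions
// within a fold so comparisons stay paired.
// [[Rcpp::export]]
NumericMatrix cpp_boot_exp(List cond_mats, IntegerMatrix idx, NumericVector t,
                           double beta_min, double beta_max, int form,
                           int ngrid) {
  int C = cond_mats.size();
  int F = idx.nrow(), P = idx.ncol();
  int T = t.size();
  NumericMatrix out(F, 2 * C);
  std::vector<NumericMatrix> mats;
  for (int c = 0; c < C; ++c) {
    NumericMatrix m = cond_mats[c];
    if (m.ncol() != T) stop("condition matrix has wrong number of trials");
    mats.push_back(m);
  }
  NumericVector avg(T);
  for (int f = 0; f < F; ++f) {
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < T; ++j) {
        double s = 0.0;
        int n = 0;
        for (int k = 0; k < P; ++k) {
          double v = mats[c](idx(f, k) - 1, j);
          if (!NumericVector::is_na(v)) { s += v; ++n; }
        }
        avg[j] = (n > 0) ? s / n : NA_REAL;
      }
      List fit = cpp_fit_exp(t, avg, beta_min, beta_max, form, ngrid);
      out(f, 2 * c) = as<double>(fit["alpha"]);
      out(f, 2 * c + 1) = as<double>(fit["beta"]);
    }
  }
  return out;
}
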