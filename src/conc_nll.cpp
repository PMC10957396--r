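#include <Rcpp.h>
using namespace Rcpp;

// Concentrated GLAMPI negative log-likelihood for one trial cell.
//
// theta = (k, g2, beta, m3, g3); sigma and nu are profiled out in closed
// form (Gaussian SD MLE given the structural parameters) and clamped to
// (1e-4, 3] and (1e-4, pi]. Out-of-bound / missing-distance trials
// (has_d false) contribute angular terms only. `geometric` selects the
// exact atan2 inbound angle instead of the model's asin closed form.
// [[Rcpp::export]]
double conc_nll_cpp(NumericVector theta,
                    NumericVector l1, NumericVector l2,
                    NumericVector T1, NumericVector T2,
                    NumericVector th2, NumericVector th3,
                    NumericVector l3, LogicalVector has_d,
                    double lbar, double tbar, bool geometric) {
  const double TWOPI = 2.0 * M_PI;
  const double LOG2PI = std::log(TWOPI);
  const int n = l1.size();
  const double k = theta[0], g2 = theta[1], beta = theta[2];
  const double m3 = theta[3], g3 = theta[4];
  double ss_a = 0.0, ss_d = 0.0;
  int na = 0, nd = 0;

  for (int i = 0; i < n; ++i) {
    const double x1 = beta * T1[i], x2 = beta * T2[i];
    const double e2 = std::exp(-x2);
    const double f1 = std::fabs(x1) < 1e-8 ? 1.0 - 0.5 * x1
                                           : -std::expm1(-x1) / x1;
    const double f2 = std::fabs(x2) < 1e-8 ? 1.0 - 0.5 * x2
                                           : (1.0 - e2) / x2;
    const double l1p = l1[i] * k * f1 * e2;
    const double l2p = l2[i] * k * f2;
    const double th2p = g2 * th2[i];
    const double ct = std::cos(th2p), st = std::sin(th2p);
    const double px = l1p + l2p * ct, py = l2p * st;
    double h = std::sqrt(px * px + py * py);
    if (h < 1e-10) h = 1e-10;
    double alpha;
    if (geometric) {
      alpha = std::fmod(std::atan2(-py, -px) - th2p, TWOPI);
      if (alpha < 0) alpha += TWOPI;
    } else {
      double u = l1p * st / h;
      if (u > 1.0) u = 1.0;
      if (u < -1.0) u = -1.0;
      alpha = M_PI - std::asin(u);
    }
    const double ra = th3[i] - g3 * alpha - (1.0 - g3) * tbar;
    ss_a += ra * ra;
    ++na;
    if (has_d[i]) {
      const double rd = l3[i] - m3 * h - (1.0 - m3) * lbar;
      ss_d += rd * rd;
      ++nd;
    }
  }

  double nu = std::sqrt(ss_a / na);
  if (nu < 1e-4) nu = 1e-4;
  if (nu > M_PI) nu = M_PI;
  double nll = ss_a / (2.0 * nu * nu) + na * (std::log(nu) + 0.5 * LOG2PI);
  if (nd > 0) {
    double sg = std::sqrt(ss_d / nd);
    if (sg < 1e-4) sg = 1e-4;
    if (sg > 3.0) sg = 3.0;
    nll += ss_d / (2.0 * sg * sg) + nd * (std::log(sg) + 0.5 * LOG2PI);
  }
  if (!R_finite(nll)) nll = 1e10;
  return nll;
}

// Analytic gradient of the concentrated NLL with respect to
// (k, g2, beta, m3, g3). By the envelope theorem the profiled sigma and
// nu can be held fixed at their closed-form optima (interior or clamped),
// so the gradient is the partial derivative of the NLL at those values.
// [[Rcpp::export]]
NumericVector conc_nll_grad_cpp(NumericVector theta,
                                NumericVector l1, NumericVector l2,
                                NumericVector T1, NumericVector T2,
                                NumericVector th2, NumericVector th3,
                                NumericVector l3, LogicalVector has_d,
                                double lbar, double tbar, bool geometric) {
  const double TWOPI = 2.0 * M_PI;
  const int n = l1.size();
  const double k = theta[0], g2 = theta[1], beta = theta[2];
  const double m3 = theta[3], g3 = theta[4];

  // pass 1: residual sums of squares for the profiled noise SDs
  double ss_a = 0.0, ss_d = 0.0;
  int na = 0, nd = 0;
  std::vector<double> ra(n), rd(n), hv(n);
  std::vector<double> dh_dk(n), dh_dg2(n), dh_db(n);
  std::vector<double> da_dk(n), da_dg2(n), da_db(n), av(n);

  for (int i = 0; i < n; ++i) {
    const double x1 = beta * T1[i], x2 = beta * T2[i];
    const double e2 = std::exp(-x2);
    double f1, f2, df1, df2;  // f(x) = (1-e^-x)/x and f'(x)
    if (std::fabs(x1) < 1e-6) {
      f1 = 1.0 - 0.5 * x1 + x1 * x1 / 6.0;
      df1 = -0.5 + x1 / 3.0;
    } else {
      f1 = -std::expm1(-x1) / x1;
      df1 = (x1 * std::exp(-x1) - (1.0 - std::exp(-x1))) / (x1 * x1);
    }
    if (std::fabs(x2) < 1e-6) {
      f2 = 1.0 - 0.5 * x2 + x2 * x2 / 6.0;
      df2 = -0.5 + x2 / 3.0;
    } else {
      f2 = (1.0 - e2) / x2;
      df2 = (x2 * e2 - (1.0 - e2)) / (x2 * x2);
    }
    const double l1p = l1[i] * k * f1 * e2;
    const double l2p = l2[i] * k * f2;
    // d l1p / d beta, d l2p / d beta
    const double dl1p_db = l1[i] * k * (df1 * T1[i] * e2 - f1 * T2[i] * e2);
    const double dl2p_db = l2[i] * k * df2 * T2[i];
    const double dl1p_dk = l1[i] * f1 * e2;
    const double dl2p_dk = l2[i] * f2;

    const double th2p = g2 * th2[i];
    const double ct = std::cos(th2p), st = std::sin(th2p);
    const double px = l1p + l2p * ct, py = l2p * st;
    double h = std::sqrt(px * px + py * py);
    if (h < 1e-10) h = 1e-10;
    const double h2 = h * h;

    // dh via (px dpx + py dpy)/h; dtheta2p/dg2 = th2
    const double dh_dl1p = px / h;
    const double dh_dl2p = (px * ct + py * st) / h;
    const double dh_dth2p = l2p * (py * ct - px * st) / h;
    dh_dk[i] = dh_dl1p * dl1p_dk + dh_dl2p * dl2p_dk;
    dh_db[i] = dh_dl1p * dl1p_db + dh_dl2p * dl2p_db;
    dh_dg2[i] = dh_dth2p * th2[i];

    double alpha, da_dl1p, da_dl2p, da_dth2p;
    if (geometric) {
      alpha = std::fmod(std::atan2(-py, -px) - th2p, TWOPI);
      if (alpha < 0) alpha += TWOPI;
      // d atan2(-py,-px) = (px dpy - py dpx)/h^2
      da_dl1p = -py / h2;
      da_dl2p = (px * st - py * ct) / h2;
      da_dth2p = (px * l2p * ct + py * l2p * st) / h2 - 1.0;
    } else {
      double u = l1p * st / h;
      if (u > 1.0) u = 1.0;
      if (u < -1.0) u = -1.0;
      alpha = M_PI - std::asin(u);
      double den = std::sqrt(std::max(1.0 - u * u, 1e-12));
      // du/d(.) then dalpha = -du/den (zero at the clamp)
      const double du_dl1p = st / h - u * dh_dl1p / h;
      const double du_dl2p = -u * dh_dl2p / h;
      const double du_dth2p = l1p * ct / h - u * dh_dth2p / h;
      da_dl1p = -du_dl1p / den;
      da_dl2p = -du_dl2p / den;
      da_dth2p = -du_dth2p / den;
    }
    da_dk[i] = da_dl1p * dl1p_dk + da_dl2p * dl2p_dk;
    da_db[i] = da_dl1p * dl1p_db + da_dl2p * dl2p_db;
    da_dg2[i] = da_dth2p * th2[i];
    av[i] = alpha;
    hv[i] = h;

    ra[i] = th3[i] - g3 * alpha - (1.0 - g3) * tbar;
    ss_a += ra[i] * ra[i];
    ++na;
    if (has_d[i]) {
      rd[i] = l3[i] - m3 * h - (1.0 - m3) * lbar;
      ss_d += rd[i] * rd[i];
      ++nd;
    }
  }

  double nu = std::sqrt(ss_a / na);
  if (nu < 1e-4) nu = 1e-4;
  if (nu > M_PI) nu = M_PI;
  double sg = nd > 0 ? std::sqrt(ss_d / nd) : 1.0;
  if (sg < 1e-4) sg = 1e-4;
  if (sg > 3.0) sg = 3.0;
  const double wa = 1.0 / (nu * nu), wd = 1.0 / (sg * sg);

  NumericVector g(5);
  for (int i = 0; i < n; ++i) {
    const double ca = -wa * ra[i];   // d(ss_a/(2 nu^2))/d th3p_i * (-1)
    g[0] += ca * g3 * da_dk[i];
    g[1] += ca * g3 * da_dg2[i];
    g[2] += ca * g3 * da_db[i];
    g[4] += ca * (av[i] - tbar);
    if (has_d[i]) {
      const double cd = -wd * rd[i];
      g[0] += cd * m3 * dh_dk[i];
      g[1] += cd * m3 * dh_dg2[i];
      g[2] += cd * m3 * dh_db[i];
      g[3] += cd * (hv[i] - lbar);
    }
  }
  return g;
}
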