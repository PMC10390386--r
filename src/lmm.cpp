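#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Profiled maximum-likelihood fitter for the random-intercept linear mixed
// model  y = X beta + Z b + e,  b_j ~ N(0, s2_b), e ~ N(0, s2).
//
// With lambda = s2_b / s2 the marginal covariance is block diagonal,
// V_j = s2 (I + lambda 1 1'), so by Sherman-Morrison
//   V_j^{-1} = (1/s2) (I - k_j 1 1'),  k_j = lambda / (1 + lambda n_j),
//   log det = n log s2 + sum_j log(1 + lambda n_j).
// beta and s2 have closed forms given lambda; the deviance is minimized over
// log(lambda) by golden-section search (plus the lambda = 0 boundary).
//
// This supports the per-time-bin likelihood-ratio analyses, where hundreds of
// thousands of such fits are required during cluster permutation; lme4 serves
// as the correctness oracle in the test suite.

namespace {

struct GroupStats {
  arma::mat XtX;   // p x p per group
  arma::vec sx;    // column sums of X per group
  double n;
};

// profiled -2 log L at variance ratio lambda; returns NA if solve fails
double prof_dev(double lambda, const std::vector<GroupStats> &gs,
                const arma::mat &Xty_g, const arma::vec &sy_g,
                const arma::vec &yty_g, double n, arma::vec *beta_out,
                double *s2_out) {
  const int G = (int)gs.size();
  const int p = (int)gs[0].XtX.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  double q0 = 0.0, ldet = 0.0;
  for (int j = 0; j < G; ++j) {
    const double k = lambda / (1.0 + lambda * gs[j].n);
    A += gs[j].XtX - k * (gs[j].sx * gs[j].sx.t());
    b += Xty_g.col(j) - k * sy_g[j] * gs[j].sx;
    q0 += yty_g[j] - k * sy_g[j] * sy_g[j];
    ldet += std::log(1.0 + lambda * gs[j].n);
  }
  arma::vec beta;
  bool ok = arma::solve(beta, A, b, arma::solve_opts::no_approx);
  if (!ok) return NA_REAL;
  const double q = q0 - arma::dot(beta, b);
  if (!(q > 0.0)) return NA_REAL;
  const double s2 = q / n;
  if (beta_out) *beta_out = beta;
  if (s2_out) *s2_out = s2;
  return n * std::log(2.0 * M_PI * s2) + ldet + n;
}

// golden-section minimum of profiled deviance over log(lambda)
double fit_one(const std::vector<GroupStats> &gs, const arma::mat &Xty_g,
               const arma::vec &sy_g, const arma::vec &yty_g, double n,
               double *lambda_out, arma::vec *beta_out, double *s2_out) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double lo = -14.0, hi = 10.0;
  double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
  double fc = prof_dev(std::exp(c), gs, Xty_g, sy_g, yty_g, n, nullptr, nullptr);
  double fd = prof_dev(std::exp(d), gs, Xty_g, sy_g, yty_g, n, nullptr, nullptr);
  if (ISNAN(fc) || ISNAN(fd)) return NA_REAL;
  for (int it = 0; it < 60 && (hi - lo) > 1e-5; ++it) {
    if (fc < fd) {
      hi = d; d = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = prof_dev(std::exp(c), gs, Xty_g, sy_g, yty_g, n, nullptr, nullptr);
      if (ISNAN(fc)) return NA_REAL;
    } else {
      lo = c; c = d; fc = fd;
      d = lo + gr * (hi - lo);
      fd = prof_dev(std::exp(d), gs, Xty_g, sy_g, yty_g, n, nullptr, nullptr);
      if (ISNAN(fd)) return NA_REAL;
    }
  }
  double lam = std::exp((lo + hi) / 2.0);
  double dev = prof_dev(lam, gs, Xty_g, sy_g, yty_g, n, beta_out, s2_out);
  // boundary: lambda = 0 (no participant variance; "singular" fit in lme4)
  arma::vec beta0;
  double s20 = 0.0;
  double dev0 = prof_dev(0.0, gs, Xty_g, sy_g, yty_g, n, &beta0, &s20);
  if (!ISNAN(dev0) && (ISNAN(dev) || dev0 < dev)) {
    dev = dev0;
    lam = 0.0;
    if (beta_out) *beta_out = beta0;
    if (s2_out) *s2_out = s20;
  }
  if (lambda_out) *lambda_out = lam;
  return dev;
}

std::vector<GroupStats> group_stats(const arma::mat &X,
                                    const arma::uvec &grp, int G) {
  const int p = (int)X.n_cols;
  std::vector<GroupStats> gs(G);
  for (int j = 0; j < G; ++j) {
    gs[j].XtX.zeros(p, p);
    gs[j].sx.zeros(p);
    gs[j].n = 0.0;
  }
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    const int j = (int)grp[i];
    const arma::rowvec xi = X.row(i);
    gs[j].XtX += xi.t() * xi;
    gs[j].sx += xi.t();
    gs[j].n += 1.0;
  }
  return gs;
}

} // namespace

// Single fit: returns logLik, beta, sigma2, lambda (var ratio), sigma2_b.
// [[Rcpp::export]]
List lmm_ml_cpp(const arma::mat &X, const arma::vec &y,
                const arma::uvec &grp, int G) {
  const double n = (double)y.n_elem;
  std::vector<GroupStats> gs = group_stats(X, grp, G);
  arma::mat Xty_g(X.n_cols, G, arma::fill::zeros);
  arma::vec sy_g(G, arma::fill::zeros), yty_g(G, arma::fill::zeros);
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    const int j = (int)grp[i];
    Xty_g.col(j) += X.row(i).t() * y[i];
    sy_g[j] += y[i];
    yty_g[j] += y[i] * y[i];
  }
  double lambda = 0.0, s2 = 0.0;
  arma::vec beta;
  double dev = fit_one(gs, Xty_g, sy_g, yty_g, n, &lambda, &beta, &s2);
  if (ISNAN(dev))
    return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["logLik"] = -dev / 2.0,
                      _["beta"] = beta, _["sigma2"] = s2,
                      _["lambda"] = lambda, _["sigma2_b"] = lambda * s2);
}

// Many outcomes (bins), several nested designs. Y is n x B; designs is a list
// of n x p_k model matrices sharing the grouping. Returns a B x K logLik
// matrix (NA where a fit failed).
// [[Rcpp::export]]
arma::mat lmm_ml_bins_cpp(const arma::mat &Y, const List &designs,
                          const arma::uvec &grp, int G) {
  const int B = (int)Y.n_cols;
  const int K = designs.size();
  const double n = (double)Y.n_rows;
  arma::mat out(B, K);
  out.fill(NA_REAL);

  for (int k = 0; k < K; ++k) {
    const arma::mat X = as<arma::mat>(designs[k]);
    std::vector<GroupStats> gs = group_stats(X, grp, G);
    for (int b = 0; b < B; ++b) {
      arma::mat Xty_g(X.n_cols, G, arma::fill::zeros);
      arma::vec sy_g(G, arma::fill::zeros), yty_g(G, arma::fill::zeros);
      const arma::vec y = Y.col(b);
      for (arma::uword i = 0; i < y.n_elem; ++i) {
        const int j = (int)grp[i];
        Xty_g.col(j) += X.row(i).t() * y[i];
        sy_g[j] += y[i];
        yty_g[j] += y[i] * y[i];
      }
      double dev = fit_one(gs, Xty_g, sy_g, yty_g, n, nullptr, nullptr, nullptr);
      if (!ISNAN(dev)) out(b, k) = -dev / 2.0;
    }
  }
  return out;
}
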