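#include <Rcpp.h>
using namespace Rcpp;

// Sequential Monte Carlo filter for the beta-Bernoulli reversal HMM.
//
// Each particle is an exact compression of one hidden-state history into its
// sufficient statistics: current state z, reversal count r, match count m
// (trials where the correct side equalled the preferred side), and the
// truncation correction c for the [0.5, 1]-truncated beta prior on the
// preferred-side reward probability. Transition and observation predictives
// are beta-binomial / beta-Bernoulli posterior predictive means in these
// counts, so the compression is exact, not an approximation.
//
// Uses R's RNG (caller is responsible for set.seed()).

namespace {

struct Branch {
  double w;
  int z;
  double r, m, c;
};

// systematic resampling of n draws from normalized weights w (size k)
void resample_systematic(const std::vector<double> &w, int n,
                         std::vector<int> &idx) {
  idx.resize(n);
  double u0 = unif_rand() / n;
  double cum = w[0];
  int j = 0;
  int k = (int)w.size();
  for (int i = 0; i < n; ++i) {
    double u = u0 + (double)i / n;
    while (u > cum && j < k - 1) {
      ++j;
      cum += w[j];
    }
    idx[i] = j;
  }
}

void resample_multinomial(const std::vector<double> &w, int n,
                          std::vector<int> &idx) {
  idx.resize(n);
  int k = (int)w.size();
  std::vector<double> cum(k);
  double s = 0.0;
  for (int j = 0; j < k; ++j) {
    s += w[j];
    cum[j] = s;
  }
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * s;
    int j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (j >= k) j = k - 1;
    idx[i] = j;
  }
}

inline double clamp01(double p) {
  if (p < 0.0) return 0.0;
  if (p > 1.0) return 1.0;
  return p;
}

} // namespace

// [[Rcpp::export]]
List hmm_filter_cpp(IntegerVector x, double ap, double bp, double aa, double ba,
                    double c0, int n_particles, int resampler) {
  const int T = x.size();
  const int N = n_particles;

  std::vector<int> z(N, 0);
  std::vector<double> r(N, 0.0), m(N, 0.0), c(N, c0), w(N, 1.0 / N);

  NumericVector post_z1(T), pred_x1(T);

  std::vector<double> bw(2 * N);
  std::vector<int> bz(2 * N);
  std::vector<double> br(2 * N), bm(2 * N), bc(2 * N);
  std::vector<int> idx;

  for (int t = 1; t <= T; ++t) {
    const int xt = x[t - 1];
    const double obs_den = ap + bp + (t - 1);
    double predx1 = 0.0;

    for (int i = 0; i < N; ++i) {
      double trans1, trans0; // P(z_t = 1 / 0 | particle history)
      if (t == 1) {
        trans0 = trans1 = 0.5;
      } else {
        const double tden = aa + ba + (t - 2);
        const double stay = (ba + (t - 2) - r[i]) / tden;
        const double change = (aa + r[i]) / tden;
        if (z[i] == 1) {
          trans1 = stay;
          trans0 = change;
        } else {
          trans0 = stay;
          trans1 = change;
        }
      }

      // raw beta-Bernoulli numerators with truncation correction
      const double num_match = ap + m[i] + c[i];
      const double num_mis = bp + (t - 1) - m[i] - c[i];
      const double pmatch = clamp01(num_match / obs_den);

      // P(x_t = 1 | z_t = 1) = pmatch, P(x_t = 1 | z_t = 0) = 1 - pmatch
      predx1 += w[i] * (trans1 * pmatch + trans0 * (1.0 - pmatch));

      // branches laid out in two blocks (all z=1 first, then all z=0):
      // block layout keeps the weight sequence free of the per-particle
      // pair periodicity that would defeat systematic resampling
      for (int zb = 0; zb <= 1; ++zb) {
        const int k = (zb == 1) ? i : (N + i);
        const double trans = (zb == 1) ? trans1 : trans0;
        const bool match = (xt == zb);
        const double pobs = match ? pmatch : (1.0 - pmatch);
        bw[k] = w[i] * trans * pobs;
        bz[k] = zb;
        br[k] = r[i] + ((t > 1 && zb != z[i]) ? 1.0 : 0.0);
        bm[k] = m[i] + (match ? 1.0 : 0.0);
        const double cden = match ? num_match : num_mis;
        bc[k] = (cden > 0.0) ? 0.5 * obs_den * c[i] / cden : 0.0;
      }
    }
    pred_x1[t - 1] = predx1;

    double tot = 0.0;
    for (int k = 0; k < 2 * N; ++k) tot += bw[k];
    if (!(tot > 0.0))
      stop("all particle branches received zero probability at trial %d", t);
    double p1 = 0.0;
    for (int k = 0; k < 2 * N; ++k) {
      bw[k] /= tot;
      if (bz[k] == 1) p1 += bw[k];
    }
    post_z1[t - 1] = p1;

    if (resampler == 1)
      resample_multinomial(bw, N, idx);
    else
      resample_systematic(bw, N, idx);
    for (int i = 0; i < N; ++i) {
      const int k = idx[i];
      z[i] = bz[k];
      r[i] = br[k];
      m[i] = bm[k];
      c[i] = bc[k];
      w[i] = 1.0 / N;
    }
  }

  // one-step-ahead predictive for trial T + 1 (used by the generative agent)
  double nextpred = 0.5;
  if (T >= 1) {
    const int t = T + 1;
    const double obs_den = ap + bp + (t - 1);
    nextpred = 0.0;
    for (int i = 0; i < N; ++i) {
      const double tden = aa + ba + (t - 2);
      const double stay = (ba + (t - 2) - r[i]) / tden;
      const double change = (aa + r[i]) / tden;
      const double trans1 = (z[i] == 1) ? stay : change;
      const double trans0 = 1.0 - trans1;
      const double pmatch = clamp01((ap + m[i] + c[i]) / obs_den);
      nextpred += w[i] * (trans1 * pmatch + trans0 * (1.0 - pmatch));
    }
  }

  return List::create(_["posterior_z1"] = post_z1, _["predictive_x1"] = pred_x1,
                      _["next_predictive_x1"] = nextpred);
}
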