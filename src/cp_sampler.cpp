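#include <Rcpp.h>
using namespace Rcpp;

// Single-change-point model on a z-scored series y[0..T-1] (one value per
// minute bin, bin t+1 covering minute (t, t+1]):
//   mu1, mu2 ~ N(0, 1);  sigma ~ HalfCauchy(1);  tau ~ Uniform(0, T)
//   y_t ~ N(mu1, sigma) for t < tau, N(mu2, sigma) for t >= tau
// The likelihood is piecewise constant in tau between bin boundaries, so
// tau is updated exactly: draw the interval index k (bins 1..k in state 1)
// from its full conditional, then tau uniformly inside (k, k+1). mu1 and
// mu2 have conjugate Gaussian updates; sigma moves by random-walk
// Metropolis on log(sigma). Uses R's RNG so seeding is controlled from R.

// [[Rcpp::export]]
List cp_sampler(NumericVector y, int n_warmup, int n_draws, int n_chains,
                double sigma_prop_sd = 0.35) {
  const int T = y.size();
  if (T < 4) stop("series must have at least 4 bins");

  // cumulative sums for O(T) interval likelihoods
  std::vector<double> cy(T + 1, 0.0), cy2(T + 1, 0.0);
  for (int t = 0; t < T; ++t) {
    cy[t + 1] = cy[t] + y[t];
    cy2[t + 1] = cy2[t] + y[t] * y[t];
  }
  const double Sy = cy[T], Sy2 = cy2[T];

  NumericMatrix tau_out(n_draws, n_chains), mu1_out(n_draws, n_chains),
      mu2_out(n_draws, n_chains), sig_out(n_draws, n_chains);
  std::vector<double> logw(T);

  RNGScope scope;
  for (int ch = 0; ch < n_chains; ++ch) {
    // overdispersed starts
    double mu1 = R::rnorm(0.0, 1.0), mu2 = R::rnorm(0.0, 1.0);
    double sigma = std::exp(R::rnorm(0.0, 0.5));
    int k = 1 + (int)std::floor(R::unif_rand() * (T - 1));

    for (int it = 0; it < n_warmup + n_draws; ++it) {
      const double s2 = sigma * sigma;

      // mu1 | k: conjugate with prior N(0,1); k may be 0 (prior draw)
      {
        double prec = 1.0 + k / s2;
        double mean = (cy[k] / s2) / prec;
        mu1 = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
      // mu2 | k
      {
        int n2 = T - k;
        double prec = 1.0 + n2 / s2;
        double mean = ((Sy - cy[k]) / s2) / prec;
        mu2 = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
      // k | mu1, mu2, sigma: exact categorical over k = 0..T-1
      {
        double mx = R_NegInf;
        for (int kk = 0; kk < T; ++kk) {
          double sse1 = cy2[kk] - 2.0 * mu1 * cy[kk] + kk * mu1 * mu1;
          double sse2 = (Sy2 - cy2[kk]) - 2.0 * mu2 * (Sy - cy[kk]) +
                        (T - kk) * mu2 * mu2;
          logw[kk] = -(sse1 + sse2) / (2.0 * s2);
          if (logw[kk] > mx) mx = logw[kk];
        }
        double tot = 0.0;
        for (int kk = 0; kk < T; ++kk) {
          logw[kk] = std::exp(logw[kk] - mx);
          tot += logw[kk];
        }
        double u = R::unif_rand() * tot, acc = 0.0;
        k = T - 1;
        for (int kk = 0; kk < T; ++kk) {
          acc += logw[kk];
          if (u <= acc) { k = kk; break; }
        }
      }
      // sigma | rest: Metropolis on theta = log(sigma),
      // p(theta) = p(sigma) * sigma with HalfCauchy(1) prior
      {
        double sse = cy2[k] - 2.0 * mu1 * cy[k] + k * mu1 * mu1 +
                     (Sy2 - cy2[k]) - 2.0 * mu2 * (Sy - cy[k]) +
                     (T - k) * mu2 * mu2;
        double th = std::log(sigma);
        double th_new = th + R::rnorm(0.0, sigma_prop_sd);
        double sg_new = std::exp(th_new);
        double lp_old = -T * th - sse / (2.0 * sigma * sigma) -
                        std::log1p(sigma * sigma) + th;
        double lp_new = -T * th_new - sse / (2.0 * sg_new * sg_new) -
                        std::log1p(sg_new * sg_new) + th_new;
        if (std::log(R::unif_rand()) < lp_new - lp_old) sigma = sg_new;
      }

      if (it >= n_warmup) {
        int row = it - n_warmup;
        tau_out(row, ch) = k + R::unif_rand(); // tau ~ U(k, k+1)
        mu1_out(row, ch) = mu1;
        mu2_out(row, ch) = mu2;
        sig_out(row, ch) = sigma;
      }
    }
  }

  return List::create(
      _["tau"] = tau_out, _["mu1"] = mu1_out, _["mu2"] = mu2_out,
      _["sigma"] = sig_out);
}
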