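#include <Rcpp.h>
using namespace Rcpp;

// Binomial emission P(k | n, y) with exact handling of the boundary
// frequencies y = 0 and y = 1; lc = lchoose(n, k) precomputed.
static inline double emis(int k, int n, double lc, double y) {
  if (y <= 0.0) return (k == 0) ? 1.0 : 0.0;
  if (y >= 1.0) return (k == n) ? 1.0 : 0.0;
  return std::exp(lc + k * std::log(y) + (n - k) * std::log1p(-y));
}

// Log composite likelihood of observed pool counts in the object
// population, per site (rows) and per selection coefficient (columns).
//
// Null (s = 0): the object frequency drifts around the reference frequency
// p1 as a Gaussian with variance omega * p1 (1 - p1), truncated to [0, 1]
// with the clipped tails as point masses at the boundaries. Sweep (s > 0):
// a lineage at recombination distance r*d escapes with probability
// c = 1 - (2 N s)^(-r d / s); conditional on the pre-sweep frequency x, the
// currently-counted (alternate) allele was linked to the beneficial
// background with probability x, giving post-sweep frequency
// (1 - c) + c x, else c x. The emission is integrated over the drift
// density by Gauss-Legendre quadrature on the supplied nodes.
// [[Rcpp::export]]
NumericMatrix cpp_xpclr_loglik(NumericVector p_ref, IntegerVector alt,
                               IntegerVector depth, NumericVector dist,
                               NumericVector s_grid, double omega,
                               double n_eff, double rec_rate,
                               NumericVector nodes, NumericVector weights,
                               double sd_floor) {
  const int ns = p_ref.size();
  const int ng = s_grid.size();
  const int nq = nodes.size();
  const double clamp = 1.0 / (2.0 * nq);
  NumericMatrix ll(ns, ng);

  std::vector<double> dens(nq);
  for (int i = 0; i < ns; ++i) {
    double mu = p_ref[i];
    if (mu < clamp) mu = clamp;
    if (mu > 1.0 - clamp) mu = 1.0 - clamp;
    double sd = std::sqrt(omega * mu * (1.0 - mu));
    if (sd < sd_floor) sd = sd_floor;
    double m0 = R::pnorm(0.0, mu, sd, 1, 0);
    double m1 = R::pnorm(1.0, mu, sd, 0, 0);
    double tot = m0 + m1;
    for (int q = 0; q < nq; ++q) {
      dens[q] = weights[q] * R::dnorm(nodes[q], mu, sd, 0);
      tot += dens[q];
    }
    const int k = alt[i], n = depth[i];
    const double lc = R::lchoose((double)n, (double)k);

    for (int j = 0; j < ng; ++j) {
      const double s = s_grid[j];
      double c = 1.0;
      if (s > 0.0) {
        const double tw = 2.0 * n_eff * s;
        if (tw > 1.0) {
          c = 1.0 - std::exp(-(rec_rate * dist[i] / s) * std::log(tw));
          if (c < 0.0) c = 0.0;
          if (c > 1.0) c = 1.0;
        }
      }
      // boundary masses: pre-sweep x = 0 is pure ref-branch (y = 0),
      // x = 1 pure alt-branch (y = 1); both are sweep-invariant.
      double lik = m0 * emis(k, n, lc, 0.0) + m1 * emis(k, n, lc, 1.0);
      for (int q = 0; q < nq; ++q) {
        const double x = nodes[q];
        const double y1 = (1.0 - c) + c * x;  // alt allele hitchhikes
        const double y0 = c * x;              // ref allele hitchhikes
        lik += dens[q] * (x * emis(k, n, lc, y1) +
                          (1.0 - x) * emis(k, n, lc, y0));
      }
      lik /= tot;
      if (lik < 1e-300) lik = 1e-300;
      ll(i, j) = std::log(lik);
    }
  }
  return ll;
}
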