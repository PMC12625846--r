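#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Gaussian phylogenetic mixed model (animal model)
//
//   y = X beta + u + e,  u ~ N(0, s2p * A),  e ~ N(0, s2r * I)
//
// run in the eigenbasis of A (A = U diag(d) U'): with yt = U'y, Xt = U'X
// the rotated model has independent errors and a diagonal random-effect
// covariance, so every full conditional is cheap. The phylogenetic
// variance uses parameter expansion u = alpha * eta,
// eta ~ N(0, s2eta * diag(d)), alpha ~ N(alpha_mu, alpha_V), giving the
// half-t / half-Cauchy marginal prior on the phylogenetic standard
// deviation. Variances carry inverse-gamma priors IG(nu/2, nu*V/2)
// (the one-dimensional inverse-Wishart (V, nu) parameterization).
//
// Draws use R's RNG so set.seed() in R makes chains reproducible.

// [[Rcpp::export]]
NumericMatrix gibbs_animal(NumericVector yt, NumericMatrix Xt,
                           NumericVector d,
                           double nu_r, double V_r,
                           double nu_p, double V_p,
                           double alpha_mu, double alpha_V,
                           double beta_prec,
                           int iterations, int burn_in, int thin,
                           bool include_phylo) {
  const int n = yt.size();
  const int p = Xt.ncol();
  if (Xt.nrow() != n) stop("Xt rows must match yt length");
  const int stored = (iterations - burn_in) / thin;
  NumericMatrix out(stored, p + 2);

  // state
  std::vector<double> beta(p, 0.0), eta(n, 0.0), r1(n);
  double alpha = 1.0, s2eta = 1.0, s2r = 1.0;

  // init residual variance from the data scale
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += yt[i];
  ybar /= n;
  double yvar = 0.0;
  for (int i = 0; i < n; ++i) yvar += (yt[i] - ybar) * (yt[i] - ybar);
  yvar /= std::max(1, n - 1);
  s2r = std::max(yvar, 1e-8);
  s2eta = s2r;

  // workspace for the p x p normal solve
  std::vector<double> P(p * p), L(p * p), b(p), z(p), w(p);

  int row = 0;
  for (int it = 0; it < iterations; ++it) {
    // ---- beta | rest : precision P = X'X/s2r + beta_prec I ----
    for (int j = 0; j < p; ++j)
      for (int k = 0; k <= j; ++k) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += Xt(i, j) * Xt(i, k);
        P[j * p + k] = s / s2r + (j == k ? beta_prec : 0.0);
      }
    // rhs = X'(yt - alpha*eta)/s2r
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i)
        s += Xt(i, j) * (yt[i] - alpha * eta[i]);
      b[j] = s / s2r;
    }
    // Cholesky P = L L'
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k <= j; ++k) {
        double s = P[j * p + k];
        for (int m = 0; m < k; ++m) s -= L[j * p + m] * L[k * p + m];
        if (j == k) {
          if (s <= 0) stop("non-PD conditional precision for beta");
          L[j * p + j] = std::sqrt(s);
        } else {
          L[j * p + k] = s / L[k * p + k];
        }
      }
    }
    // solve L w = b, then L' z = w  -> mean in z
    for (int j = 0; j < p; ++j) {
      double s = b[j];
      for (int m = 0; m < j; ++m) s -= L[j * p + m] * w[m];
      w[j] = s / L[j * p + j];
    }
    for (int j = p - 1; j >= 0; --j) {
      double s = w[j];
      for (int m = j + 1; m < p; ++m) s -= L[m * p + j] * z[m];
      z[j] = s / L[j * p + j];
    }
    // beta = mean + L'^{-1} eps
    for (int j = 0; j < p; ++j) w[j] = R::norm_rand();
    for (int j = p - 1; j >= 0; --j) {
      double s = w[j];
      for (int m = j + 1; m < p; ++m) s -= L[m * p + j] * beta[m];
      beta[j] = s / L[j * p + j];
    }
    for (int j = 0; j < p; ++j) beta[j] += z[j];

    // residual without the random effect: r1 = yt - Xt beta
    for (int i = 0; i < n; ++i) {
      double s = yt[i];
      for (int j = 0; j < p; ++j) s -= Xt(i, j) * beta[j];
      r1[i] = s;
    }

    if (include_phylo) {
      // ---- eta_i | rest ----
      const double a2 = alpha * alpha;
      for (int i = 0; i < n; ++i) {
        double di = d[i] > 1e-12 ? d[i] : 1e-12;
        double prec = a2 / s2r + 1.0 / (s2eta * di);
        double mean = (alpha * r1[i] / s2r) / prec;
        eta[i] = mean + R::norm_rand() / std::sqrt(prec);
      }
      // ---- alpha | rest ----
      double se2 = 0.0, ser = 0.0;
      for (int i = 0; i < n; ++i) {
        se2 += eta[i] * eta[i];
        ser += eta[i] * r1[i];
      }
      double prec_a = se2 / s2r + 1.0 / alpha_V;
      double mean_a = (ser / s2r + alpha_mu / alpha_V) / prec_a;
      alpha = mean_a + R::norm_rand() / std::sqrt(prec_a);
      // ---- s2eta | rest : IG((n + nu_p)/2, (nu_p V_p + sum eta^2/d)/2) ----
      double q = 0.0;
      for (int i = 0; i < n; ++i) {
        double di = d[i] > 1e-12 ? d[i] : 1e-12;
        q += eta[i] * eta[i] / di;
      }
      double shape = 0.5 * (n + nu_p);
      double rate = 0.5 * (nu_p * V_p + q);
      s2eta = rate / R::rgamma(shape, 1.0);
    }

    // ---- s2r | rest ----
    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = r1[i] - (include_phylo ? alpha * eta[i] : 0.0);
      ssr += e * e;
    }
    {
      double shape = 0.5 * (n + nu_r);
      double rate = 0.5 * (nu_r * V_r + ssr);
      s2r = rate / R::rgamma(shape, 1.0);
    }
    if (!std::isfinite(s2r) || (include_phylo && !std::isfinite(s2eta))) {
      stop("divergent variance draw at iteration %d (s2r=%g, s2eta=%g)",
           it + 1, s2r, s2eta);
    }

    if (it >= burn_in && ((it - burn_in) % thin) == (thin - 1)) {
      if (row < stored) {
        for (int j = 0; j < p; ++j) out(row, j) = beta[j];
        out(row, p) = include_phylo ? alpha * alpha * s2eta : 0.0;
        out(row, p + 1) = s2r;
        ++row;
      }
    }
  }
  return out;
}
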