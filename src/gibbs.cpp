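#include <Rcpp.h>
using namespace Rcpp;

// One draw from N(mu, 1) truncated to the positive (pos = true) or negative
// half-line, by inverse-CDF sampling; clamped when the untruncated mass in the
// admissible region underflows.
static double rtnorm01(double mu, bool pos) {
  double u = R::runif(0.0, 1.0);
  double z;
  if (pos) {
    double plo = R::pnorm(0.0, mu, 1.0, 1, 0);     // P(Z < 0)
    z = R::qnorm(plo + u * (1.0 - plo), mu, 1.0, 1, 0);
    if (!R_FINITE(z) || z <= 0.0) z = (mu > 0.0 ? mu : 0.0) + 1e-10;
  } else {
    double plo = R::pnorm(0.0, mu, 1.0, 1, 0);
    z = R::qnorm(u * plo, mu, 1.0, 1, 0);
    if (!R_FINITE(z) || z >= 0.0) z = (mu < 0.0 ? mu : 0.0) - 1e-10;
  }
  return z;
}

// Albert-Chib data-augmentation Gibbs sampler for binary probit regression
// with a single scalar covariate m: P(y = 1) = Phi(alpha + beta * m).
// Conjugate N(b0, B0) prior on (alpha, beta). Uses R's RNG, so draws are
// reproducible under set.seed() on the R side.
//
// [[Rcpp::export(name = ".gibbs_probit_cpp")]]
NumericMatrix gibbs_probit_cpp(IntegerVector y, NumericVector m,
                               NumericVector prior_mean, NumericMatrix prior_prec,
                               int n_draws, int burn_in) {
  const int n = y.size();
  // X = [1, m]; posterior precision A = X'X + P0 (constant across iterations)
  double a11 = n + prior_prec(0, 0);
  double a12 = prior_prec(0, 1), a22 = prior_prec(1, 1);
  double sm = 0.0, smm = 0.0;
  for (int i = 0; i < n; ++i) { sm += m[i]; smm += m[i] * m[i]; }
  a12 += sm; a22 += smm;
  double det = a11 * a22 - a12 * a12;
  if (det <= 0.0) stop("posterior precision not positive definite");
  // posterior covariance B = A^{-1} and its (lower) Cholesky factor
  double b11 = a22 / det, b12 = -a12 / det, b22 = a11 / det;
  double l11 = std::sqrt(b11);
  double l21 = b12 / l11;
  double l22 = std::sqrt(b22 - l21 * l21);
  // prior contribution P0 * b0 to the posterior mean
  double p1 = prior_prec(0, 0) * prior_mean[0] + prior_prec(0, 1) * prior_mean[1];
  double p2 = prior_prec(1, 0) * prior_mean[0] + prior_prec(1, 1) * prior_mean[1];

  double alpha = 0.0, beta = 0.0;
  NumericMatrix out(n_draws, 2);
  int total = n_draws + burn_in;
  for (int it = 0; it < total; ++it) {
    // latent z_i ~ N(alpha + beta m_i, 1) truncated by the observed class
    double sz = 0.0, szm = 0.0;
    for (int i = 0; i < n; ++i) {
      double mu = alpha + beta * m[i];
      double z = rtnorm01(mu, y[i] == 1);
      sz += z; szm += z * m[i];
    }
    // (alpha, beta) | z ~ N(B (X'z + P0 b0), B)
    double c1 = sz + p1, c2 = szm + p2;
    double mu1 = b11 * c1 + b12 * c2;
    double mu2 = b12 * c1 + b22 * c2;
    double e1 = R::norm_rand(), e2 = R::norm_rand();
    alpha = mu1 + l11 * e1;
    beta = mu2 + l21 * e1 + l22 * e2;
    if (it >= burn_in) {
      out(it - burn_in, 0) = alpha;
      out(it - burn_in, 1) = beta;
    }
  }
  colnames(out) = CharacterVector::create("alpha", "beta");
  return out;
}
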