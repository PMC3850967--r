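# Independent oracles and small fixture builders shared across tests.

# Brute-force 2-D quadrature posterior for the binary probit model
# P(y=1) = Phi(alpha + beta*m) with independent normal priors: posterior means
# of (alpha, beta) on a regular grid. Completely independent of the Gibbs path.
probit_quadrature_means <- function(scores, y, prior_mean = c(0, 0),
                                    prior_sd = c(10, 10), lim = 8, n_grid = 401) {
  a <- seq(prior_mean[1] - lim, prior_mean[1] + lim, length.out = n_grid)
  b <- seq(prior_mean[2] - lim, prior_mean[2] + lim, length.out = n_grid)
  ll <- matrix(0, n_grid, n_grid)
  for (j in seq_len(n_grid)) {
    eta <- a + matrix(b[j] * scores, n_grid, length(scores), byrow = TRUE)
    ll[, j] <- rowSums(t(t(pnorm(eta, log.p = TRUE)) * y) +
                       t(t(pnorm(-eta, log.p = TRUE)) * (1 - y)))
  }
  ll <- ll + dnorm(a, prior_mean[1], prior_sd[1], log = TRUE) +
    rep(dnorm(b, prior_mean[2], prior_sd[2], log = TRUE), each = n_grid)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  c(alpha = sum(rowSums(w) * a), beta = sum(colSums(w) * b))
}

# Fixed non-separable 20-sample toy set used wherever the probit oracle is
# compared against the sampler.
probit_toy <- function() {
  list(scores = round(seq(-2, 2, length.out = 20), 2),
       y = c(0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 1, 0, 1, 1, 1, 1, 1))
}

# Minimal expr_matrix from a plain matrix (log2 by default).
toy_expr <- function(values, scale = "log2", annotations = NULL) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, scale = scale, annotations = annotations)
}

# Activity table straight from a rescaled-style score matrix: inverts the
# log-minmax so that the stored rescaled scores equal `scores` exactly up to
# monotone mapping (used where only threshold crossings matter).
activity_from_scores <- function(scores, dataset_id = "toy") {
  raw <- exp(scores - 1)   # strictly increasing map into (e^-1, 1)
  raw <- raw * 0.9 + 0.05  # keep well inside (0, 1)
  if (is.null(rownames(scores))) rownames(raw) <- sprintf("s%03d", seq_len(nrow(scores)))
  activity_table(raw, dataset_id = dataset_id)
}
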