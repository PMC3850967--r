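#' Select signature genes by a regularized two-class statistic
#'
#' Ranks probes by the absolute value of a regularized signal-to-noise
#' statistic, `(mean_1 - mean_0) / (s_pooled + s0)`, where `s_pooled` is the
#' pooled within-class standard deviation and the stabilizer `s0` is the median
#' pooled SD across probes (guarding against near-zero denominators). Returns
#' the top `n_genes` probe ids in descending order of |statistic|, with ties
#' broken lexicographically by probe id for determinism.
#'
#' @param m an `expr_matrix` (filtered, normalized, log2 scale).
#' @param class binary 0/1 vector (or two-level factor) over samples; 1 marks
#'   the pathway-activated class.
#' @param n_genes number of probes to select (at least 1).
#' @return Character vector of selected probe ids, with the per-probe
#'   statistics attached as attribute `statistic`.
#' @export
select_signature_genes <- function(m, class, n_genes = 200) {
  stopifnot(inherits(m, "expr_matrix"))
  cl <- .as_binary_class(class, ncol(m$values))
  if (n_genes < 1 || n_genes > nrow(m$values))
    .stopf("n_genes must be between 1 and the probe count (%d)", nrow(m$values))
  n1 <- sum(cl == 1); n0 <- sum(cl == 0)
  if (n1 < 2 || n0 < 2) .stopf("each class needs at least 2 samples")
  v <- m$values
  m1 <- rowMeans(v[, cl == 1, drop = FALSE])
  m0 <- rowMeans(v[, cl == 0, drop = FALSE])
  ss1 <- rowSums((v[, cl == 1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((v[, cl == 0, drop = FALSE] - m0)^2)
  sp <- sqrt((ss1 + ss0) / (n1 + n0 - 2))
  s0 <- median(sp)
  stat <- (m1 - m0) / (sp + s0)
  ord <- order(-abs(stat), rownames(v))
  sel <- rownames(v)[ord[seq_len(n_genes)]]
  attr(sel, "statistic") <- stat[sel]
  sel
}

# internal: coerce a class label vector to 0/1 integers
.as_binary_class <- function(class, n) {
  if (is.factor(class)) {
    if (nlevels(droplevels(class)) != 2) .stopf("class factor must have exactly 2 levels")
    class <- as.integer(class == levels(droplevels(class))[2])
  }
  class <- as.integer(class)
  if (length(class) != n) .stopf("class labels length %d != %d samples", length(class), n)
  if (anyNA(class) || !all(class %in% c(0L, 1L))) .stopf("class labels must be 0/1")
  if (length(unique(class)) < 2) .stopf("both classes must be present")
  class
}

#' Compute the SVD metagene of a signature gene set
#'
#' Standardizes each selected gene to mean 0, SD 1 across the training samples
#' and takes the singular value decomposition of the resulting genes-by-samples
#' matrix. The metagene loading is the first left singular vector `u` (unit
#' length); per-sample metagene scores are `d * v1`, identically `u' x_j` for
#' the standardized profile `x_j`. The sign is oriented so that the mean score
#' of the activated class is at least that of the control class.
#'
#' @param values numeric matrix restricted to the signature genes
#'   (genes x samples, log2 scale, not yet standardized).
#' @param class binary 0/1 vector over samples.
#' @return List with `u` (named loading vector), `d` (first singular value),
#'   `scores` (named per-sample metagene scores), `orientation` (+1 or -1, the
#'   sign already folded into `u` and `scores`), `gene_means`, `gene_sds`.
#' @export
compute_metagene <- function(values, class) {
  cl <- .as_binary_class(class, ncol(values))
  mu <- rowMeans(values)
  sdv <- apply(values, 1, sd)
  if (any(sdv == 0))
    .stopf("zero-variance gene(s) in training data: %s",
           paste(rownames(values)[sdv == 0], collapse = ", "))
  x <- (values - mu) / sdv
  s <- svd(x)
  u <- s$u[, 1]
  d <- s$d[1]
  scores <- s$v[, 1] * d
  orientation <- if (mean(scores[cl == 1]) >= mean(scores[cl == 0])) 1 else -1
  u <- u * orientation
  scores <- scores * orientation
  names(u) <- rownames(values)
  names(scores) <- colnames(values)
  list(u = u, d = d, scores = scores, orientation = orientation,
       gene_means = mu, gene_sds = sdv)
}

#' Fit a Bayesian binary probit regression by Gibbs sampling
#'
#' Albert–Chib data augmentation for the model `P(y_j = 1) = Phi(alpha +
#' beta * m_j)`: latent truncated-normal variables are drawn given the
#' coefficients, then `(alpha, beta)` given the latents from the conjugate
#' normal update under a `N(prior_mean, prior_cov)` prior. Draws after burn-in
#' are returned; with the same seed the chain is fully reproducible.
#'
#' @param scores numeric vector of metagene scores.
#' @param labels binary 0/1 outcome vector.
#' @param prior_mean,prior_cov normal prior on `(alpha, beta)`; the default is
#'   a weakly informative zero-mean prior with covariance `100 * I`.
#' @param n_draws number of retained posterior draws.
#' @param burn_in number of discarded initial iterations.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return Numeric matrix (`n_draws` x 2) with columns `alpha`, `beta`.
#' @export
fit_probit_bayes <- function(scores, labels, prior_mean = c(0, 0),
                             prior_cov = diag(100, 2), n_draws = 5000,
                             burn_in = 1000, seed = NULL) {
  if (any(!is.finite(scores))) .stopf("non-finite metagene scores")
  y <- .as_binary_class(labels, length(scores))
  prior_prec <- tryCatch(chol2inv(chol(prior_cov)),
                         error = function(e) .stopf("prior covariance must be positive definite"))
  if (!is.null(seed)) set.seed(seed)
  .gibbs_probit_cpp(as.integer(y), as.numeric(scores), as.numeric(prior_mean),
                    prior_prec, as.integer(n_draws), as.integer(burn_in))
}

# internal: posterior-mean activation probability for metagene scores
# (mean over draws of Phi(alpha + beta * m), not Phi at the posterior mean).
# Phi underflows to exactly 0/1 in double precision for |eta| beyond ~38, so
# the result is clamped to the open interval required by the downstream log
# rescaling; the clamp bound is the probability floor of the activity scale.
.prob_floor <- 1e-15
.posterior_prob <- function(draws, scores) {
  eta <- outer(draws[, "beta"], scores) + draws[, "alpha"]
  p <- colMeans(pnorm(eta))
  p <- pmin(pmax(p, .prob_floor), 1 - .prob_floor)
  names(p) <- names(scores)
  p
}

#' Train a pathway signature
#'
#' The central model fit: from a two-class training expression matrix
#' (control versus pathway-activated samples) it (1) selects signature genes by
#' the regularized two-class statistic, (2) summarizes them as an SVD metagene,
#' and (3) fits a Bayesian binary probit regression of class on metagene score
#' by Gibbs sampling. The returned object carries everything needed to project
#' the signature onto an independent dataset with [predict.pathway_signature()].
#'
#' @param m an `expr_matrix` of training data (log2 scale, filtered and
#'   normalized upstream).
#' @param class binary 0/1 vector (or the name of an annotation column) giving
#'   the training classes; 1 = pathway-activated.
#' @param n_genes number of signature genes (default 200).
#' @param prior_mean,prior_cov prior on the probit coefficients.
#' @param n_draws,burn_in Gibbs chain settings (defaults 5000 and 1000).
#' @param seed integer seed for the sampler.
#' @param pathway optional pathway name stored on the object.
#' @return An object of class `pathway_signature`: a list with the selected
#'   `gene_ids`, per-gene `gene_means`/`gene_sds`, the loading vector `u` and
#'   singular value `d`, the `orientation` sign, the posterior `draws`, the
#'   training `scores` and fitted probabilities, and the `config` used.
#' @seealso [predict.pathway_signature()], [run_loocv()]
#' @export
train_signature <- function(m, class, n_genes = 200, prior_mean = c(0, 0),
                            prior_cov = diag(100, 2), n_draws = 5000,
                            burn_in = 1000, seed = NULL, pathway = "pathway") {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.character(class) && length(class) == 1) class <- .get_annotation(m, class)
  cl <- .as_binary_class(class, ncol(m$values))
  genes <- select_signature_genes(m, cl, n_genes)
  mg <- compute_metagene(m$values[genes, , drop = FALSE], cl)
  draws <- fit_probit_bayes(mg$scores, cl, prior_mean, prior_cov,
                            n_draws, burn_in, seed)
  fitted <- .posterior_prob(draws, mg$scores)
  structure(list(
    pathway = pathway,
    gene_ids = genes,
    gene_means = mg$gene_means,
    gene_sds = mg$gene_sds,
    u = mg$u,
    d = mg$d,
    orientation = mg$orientation,
    draws = draws,
    train_scores = mg$scores,
    train_labels = cl,
    fitted_prob = fitted,
    config = list(n_genes = n_genes, prior_mean = prior_mean,
                  prior_cov = prior_cov, n_draws = n_draws,
                  burn_in = burn_in, seed = seed, n_metagenes = 1L)),
    class = "pathway_signature")
}

#' Leave-one-out cross-validation of a pathway signature
#'
#' For each training sample in turn, the entire fit — gene selection, metagene,
#' probit regression — is recomputed on the remaining samples and the held-out
#' sample's activation probability is predicted from that model. Accuracy is
#' evaluated at the 0.5 probability threshold.
#'
#' @inheritParams train_signature
#' @return List with `probabilities` (held-out, per sample), `predicted`
#'   (0/1 at threshold 0.5), `labels`, `confusion` (2x2 table), `accuracy`.
#' @export
run_loocv <- function(m, class, n_genes = 200, prior_mean = c(0, 0),
                      prior_cov = diag(100, 2), n_draws = 5000,
                      burn_in = 1000, seed = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.character(class) && length(class) == 1) class <- .get_annotation(m, class)
  cl <- .as_binary_class(class, ncol(m$values))
  if (sum(cl == 1) < 3 || sum(cl == 0) < 3)
    .stopf("LOOCV needs at least 3 samples per class")
  n <- ncol(m$values)
  if (!is.null(seed)) set.seed(seed)
  probs <- numeric(n)
  for (j in seq_len(n)) {
    tr <- .subset_samples(m, setdiff(seq_len(n), j))
    fit <- train_signature(tr, cl[-j], n_genes = n_genes,
                           prior_mean = prior_mean, prior_cov = prior_cov,
                           n_draws = n_draws, burn_in = burn_in, seed = NULL)
    # held-out sample standardized with the training-fold parameters
    x <- (m$values[fit$gene_ids, j] - fit$gene_means) / fit$gene_sds
    score <- sum(fit$u * x)
    probs[j] <- .posterior_prob(fit$draws, setNames(score, colnames(m$values)[j]))
  }
  names(probs) <- colnames(m$values)
  pred <- as.integer(probs > 0.5)
  confusion <- table(truth = factor(cl, c(0, 1)), predicted = factor(pred, c(0, 1)))
  list(probabilities = probs, predicted = pred, labels = cl,
       confusion = confusion, accuracy = mean(pred == cl))
}
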