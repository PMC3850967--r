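#' @export
print.pathway_signature <- function(x, ...) {
  cat(sprintf("Pathway signature '%s'\n", x$pathway))
  cat(sprintf("  %d signature genes; metagene singular value d = %.3f\n",
              length(x$gene_ids), x$d))
  cm <- colMeans(x$draws)
  cat(sprintf("  probit posterior means: alpha = %.3f, beta = %.3f (%d draws)\n",
              cm["alpha"], cm["beta"], nrow(x$draws)))
  cat(sprintf("  training: %d control / %d activated samples\n",
              sum(x$train_labels == 0), sum(x$train_labels == 1)))
  invisible(x)
}

#' @export
summary.pathway_signature <- function(object, ...) {
  qs <- apply(object$draws, 2, quantile, c(0.025, 0.5, 0.975))
  out <- list(
    pathway = object$pathway,
    n_genes = length(object$gene_ids),
    d = object$d,
    coefficients = rbind(mean = colMeans(object$draws), qs),
    train_accuracy = mean(as.integer(object$fitted_prob > 0.5) == object$train_labels),
    config = object$config)
  class(out) <- "summary.pathway_signature"
  out
}

#' @export
print.summary.pathway_signature <- function(x, ...) {
  cat(sprintf("Pathway signature '%s' (%d genes, d = %.3f)\n",
              x$pathway, x$n_genes, x$d))
  cat("Posterior for (alpha, beta):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("Training accuracy at p > 0.5: %.3f\n", x$train_accuracy))
  invisible(x)
}

#' Posterior-mean probit coefficients
#' @param object a `pathway_signature` fit.
#' @param ... unused.
#' @return Named vector with posterior means of `alpha` and `beta`.
#' @export
coef.pathway_signature <- function(object, ...) colMeans(object$draws)

#' @export
fitted.pathway_signature <- function(object, ...) object$fitted_prob

#' Plot a pathway signature fit
#'
#' Training metagene scores against fitted activation probabilities, with the
#' posterior-mean probit curve; control and activated samples distinguished.
#'
#' @param x a `pathway_signature` fit.
#' @param ... passed to [plot()].
#' @export
plot.pathway_signature <- function(x, ...) {
  s <- x$train_scores
  plot(s, x$fitted_prob, col = ifelse(x$train_labels == 1, "firebrick", "steelblue"),
       pch = 19, xlab = "metagene score", ylab = "P(activated)",
       main = sprintf("signature '%s'", x$pathway), ylim = c(0, 1), ...)
  grid_m <- seq(min(s), max(s), length.out = 200)
  lines(grid_m, .posterior_prob(x$draws, grid_m), lwd = 2)
  invisible(x)
}

#' Match signature genes into a target dataset
#'
#' Maps the signature genes onto the rows of a target expression matrix.
#' The loading vector is restricted to the matched genes and re-normalized to
#' unit length; projection fails if the matched fraction falls below
#' `min_coverage`.
#'
#' @param model a `pathway_signature`.
#' @param m target `expr_matrix`.
#' @param min_coverage minimum matched fraction of signature genes (default 0.5).
#' @return List with `index` (target row indices, named by gene), `coverage`
#'   (matched fraction), and `u` (restricted, re-normalized loading vector).
#' @export
match_genes <- function(model, m, min_coverage = 0.5) {
  stopifnot(inherits(model, "pathway_signature"), inherits(m, "expr_matrix"))
  idx <- match(model$gene_ids, rownames(m$values))
  hit <- !is.na(idx)
  coverage <- mean(hit)
  if (coverage < min_coverage)
    .stopf("only %.0f%% of signature genes found in target (%.0f%% missing); floor is %.0f%%",
           100 * coverage, 100 * (1 - coverage), 100 * min_coverage)
  u <- model$u[hit]
  u <- u / sqrt(sum(u^2))
  list(index = setNames(idx[hit], model$gene_ids[hit]), coverage = coverage, u = u)
}

#' Project a pathway signature onto new expression data
#'
#' Computes per-sample pathway-activation probabilities for an independent
#' dataset: signature genes are matched into the target, each matched gene is
#' standardized (by default within the target dataset, the scale-robust choice
#' when projecting across platforms; optionally with the training parameters),
#' the metagene score `u' x_j` is formed, and the probability is the posterior
#' mean of `Phi(alpha + beta * m_j)` over the stored draws.
#'
#' @param object a `pathway_signature` fit.
#' @param newdata an `expr_matrix` (log2 scale, quantile normalized) or a
#'   numeric genes-by-samples matrix.
#' @param standardize `"target"` (per-gene mean/SD within `newdata`) or
#'   `"training"` (the training-fold parameters).
#' @param min_coverage minimum matched gene fraction (see [match_genes()]).
#' @param ... unused.
#' @return Named numeric vector of raw activation probabilities in (0, 1),
#'   with attributes `coverage` and `scores` (metagene scores).
#' @export
predict.pathway_signature <- function(object, newdata,
                                      standardize = c("target", "training"),
                                      min_coverage = 0.5, ...) {
  standardize <- match.arg(standardize)
  if (is.matrix(newdata)) newdata <- expression_matrix(newdata, scale = "log2")
  stopifnot(inherits(newdata, "expr_matrix"))
  mm <- match_genes(object, newdata, min_coverage)
  v <- newdata$values[mm$index, , drop = FALSE]
  if (standardize == "target") {
    mu <- rowMeans(v)
    sdv <- apply(v, 1, sd)
  } else {
    mu <- object$gene_means[names(mm$index)]
    sdv <- object$gene_sds[names(mm$index)]
  }
  u <- mm$u
  if (any(sdv == 0)) {
    .warnf("dropping %d zero-variance signature gene(s) in target", sum(sdv == 0))
    keep <- sdv > 0
    if (!any(keep)) .stopf("all signature genes have zero variance in target")
    v <- v[keep, , drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
    u <- u[keep]; u <- u / sqrt(sum(u^2))
  }
  x <- (v - mu) / sdv
  scores <- drop(crossprod(x, u))
  names(scores) <- colnames(v)
  p <- .posterior_prob(object$draws, scores)
  attr(p, "coverage") <- mm$coverage
  attr(p, "scores") <- scores
  p
}
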