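#' Pairwise Spearman correlations between pathway activities
#'
#' Spearman rank correlation (average ranks for ties) between every pair of
#' pathway score columns, with two-sided p-values from the large-sample
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. A constant pathway has undefined rank correlation and is reported
#' as `NA` with a warning.
#'
#' @param a an [activity_table()] with at least 3 samples.
#' @param method correlation method; only `"spearman"` is offered.
#' @return List with symmetric matrices `r` and `p` and the sample size `n`.
#' @export
pairwise_correlations <- function(a, method = "spearman") {
  stopifnot(inherits(a, "activity_table"))
  method <- match.arg(method)
  x <- a$rescaled
  n <- nrow(x)
  if (n < 3) .stopf("need at least 3 samples for correlations")
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  if (any(const))
    .warnf("constant pathway column(s): %s; correlations reported as NA",
           paste(colnames(x)[const], collapse = ", "))
  r <- suppressWarnings(cor(x, method = "spearman"))
  r[const, ] <- NA; r[, const] <- NA
  diag(r)[!const] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(r = r, p = p, n = n)
}

#' Classify samples into activation quadrants for a pathway pair
#'
#' Declares a pathway "active" in a sample when its rescaled score strictly
#' exceeds `threshold` (a score exactly at the threshold is inactive), and
#' labels each sample `both`, `A_only`, `B_only`, or `neither`. The summary
#' reports quadrant counts, marginal activation fractions, the observed
#' co-activation fraction, the expectation under independence (the exact
#' product of the marginals), and the one-sided co-activation deficit p-value
#' from [coactivation_deficit_test()].
#'
#' @param a an [activity_table()].
#' @param pathway_A,pathway_B pathway column names.
#' @param threshold activation cutoff on the rescaled score (default 0.5).
#' @return List with `labels` (per-sample factor) and `summary`, an object of
#'   class `quadrant_summary`.
#' @export
classify_quadrants <- function(a, pathway_A, pathway_B, threshold = 0.5) {
  stopifnot(inherits(a, "activity_table"))
  for (p in c(pathway_A, pathway_B))
    if (!p %in% a$pathways) .stopf("pathway '%s' not present in activity table", p)
  actA <- a$rescaled[, pathway_A] > threshold
  actB <- a$rescaled[, pathway_B] > threshold
  labels <- factor(ifelse(actA & actB, "both",
                   ifelse(actA, "A_only", ifelse(actB, "B_only", "neither"))),
                   levels = c("both", "A_only", "B_only", "neither"))
  counts <- table(labels)
  qs <- quadrant_summary(both = counts[["both"]], A_only = counts[["A_only"]],
                         B_only = counts[["B_only"]], neither = counts[["neither"]],
                         threshold = threshold,
                         pathways = c(pathway_A, pathway_B))
  list(labels = setNames(labels, a$sample_ids), summary = qs)
}

#' Quadrant summary for a pathway pair
#'
#' Builds the 2x2 activation summary from quadrant counts. The expected
#' co-activation fraction under independence is exactly the product of the two
#' marginal activation fractions.
#'
#' @param both,A_only,B_only,neither quadrant counts.
#' @param threshold the activation cutoff used (metadata).
#' @param pathways length-2 character vector of pathway names (metadata).
#' @return Object of class `quadrant_summary`.
#' @export
quadrant_summary <- function(both, A_only, B_only, neither,
                             threshold = 0.5, pathways = c("A", "B")) {
  counts <- c(both = both, A_only = A_only, B_only = B_only, neither = neither)
  if (any(counts < 0) || any(counts != round(counts))) .stopf("counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) .stopf("empty summary")
  marginal_A <- (both + A_only) / n
  marginal_B <- (both + B_only) / n
  out <- structure(list(
    counts = counts, n = n, threshold = threshold, pathways = pathways,
    observed_coactivation = both / n,
    marginal_A = marginal_A, marginal_B = marginal_B,
    expected_coactivation = marginal_A * marginal_B,
    p_value = NA_real_), class = "quadrant_summary")
  out$p_value <- coactivation_deficit_test(out)
  out
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("Quadrant summary: %s vs %s (threshold %g, n = %d)\n",
              x$pathways[1], x$pathways[2], x$threshold, x$n))
  print(x$counts)
  cat(sprintf("observed co-activation %.4f vs expected %.4f (marginals %.4f, %.4f)\n",
              x$observed_coactivation, x$expected_coactivation,
              x$marginal_A, x$marginal_B))
  cat(sprintf("co-activation deficit p = %.4g\n", x$p_value))
  invisible(x)
}

#' One-sided co-activation deficit test
#'
#' Tests whether the number of co-activated samples falls below what
#' independent activation at the marginal rates would produce. The default is
#' the one-sided Fisher exact test on the 2x2 activation table (the
#' hypergeometric tail conditioning on both margins), the standard exact test
#' for mutual exclusivity; because it conditions on the estimated margins it
#' holds its nominal level. Two alternatives are provided: `"binomial"`, the
#' exact binomial tail of the co-activation count against the
#' product-of-marginals rate (transparent, but conservative because the null
#' rate is estimated from the same table), and `"chisq"`, the one-sided
#' chi-square approximation.
#'
#' @param q a `quadrant_summary`.
#' @param method `"fisher"` (default), `"binomial"`, or `"chisq"`.
#' @return One-sided p-value for a deficit of co-activation.
#' @export
coactivation_deficit_test <- function(q, method = c("fisher", "binomial", "chisq")) {
  stopifnot(inherits(q, "quadrant_summary"))
  method <- match.arg(method)
  k <- q$counts[["both"]]
  p0 <- q$expected_coactivation
  if (p0 == 0) return(if (k > 0) 0 else 1)
  if (p0 >= 1) return(1)
  switch(method,
    fisher = {
      nA <- k + q$counts[["A_only"]]   # samples with A active
      nB <- k + q$counts[["B_only"]]   # samples with B active
      stats::phyper(k, nA, q$n - nA, nB)
    },
    binomial = pbinom(k, q$n, p0),
    chisq = {
      exp_k <- q$n * p0
      if (k >= exp_k) return(1)        # no deficit
      stat <- (k - exp_k)^2 / (exp_k * (1 - p0))
      stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2
    })
}

#' Association of pathway activity with tumor subtypes
#'
#' One-way fixed-effects ANOVA of a pathway's rescaled activity scores across
#' subtype groups, plus a "high-activation" enrichment table: among the
#' samples whose scores strictly exceed `threshold` jointly for every pathway
#' in `high`, the fraction belonging to each subtype. Subtypes with fewer than
#' 2 samples are dropped with a warning.
#'
#' @param a an [activity_table()].
#' @param subtypes character or factor vector of subtype labels, aligned with
#'   the table's samples.
#' @param pathway pathway whose scores are tested by ANOVA.
#' @param high character vector of pathways whose joint high activation
#'   defines the enrichment set (default: `pathway`).
#' @param threshold activation cutoff (default 0.5).
#' @return List with `F`, `p`, `df`, `subtype_means`, `enrichment` (fraction
#'   of high-activation samples per subtype), `n_high`.
#' @export
subtype_association <- function(a, subtypes, pathway, high = pathway,
                                threshold = 0.5) {
  stopifnot(inherits(a, "activity_table"))
  if (!pathway %in% a$pathways) .stopf("pathway '%s' not present", pathway)
  subtypes <- factor(as.character(subtypes))
  if (length(subtypes) != nrow(a$raw))
    .stopf("subtype labels length %d != %d samples", length(subtypes), nrow(a$raw))
  sizes <- table(subtypes)
  small <- names(sizes)[sizes < 2]
  keep <- !(subtypes %in% small)
  if (length(small)) {
    .warnf("dropping subtype(s) with < 2 samples: %s", paste(small, collapse = ", "))
    subtypes <- droplevels(subtypes[keep])
  } else subtypes <- droplevels(subtypes)
  if (nlevels(subtypes) < 2) .stopf("need at least 2 subtypes with >= 2 samples")
  score <- a$rescaled[keep, pathway]
  fit <- aov(score ~ subtypes)
  tab <- anova(fit)
  high_mask <- rep(TRUE, sum(keep))
  for (p in high) {
    if (!p %in% a$pathways) .stopf("pathway '%s' not present", p)
    high_mask <- high_mask & a$rescaled[keep, p] > threshold
  }
  enrichment <- if (any(high_mask))
    prop.table(table(subtypes[high_mask])) else setNames(rep(NA_real_, nlevels(subtypes)),
                                                         levels(subtypes))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(tab$Df[1], tab$Df[2]),
       subtype_means = tapply(score, subtypes, mean),
       enrichment = enrichment, n_high = sum(high_mask))
}
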