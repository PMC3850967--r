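#' Genomic matrix container
#'
#' Gene/probe-by-sample matrix of copy-number log2 tumor/normal ratios or
#' methylation values, optionally carrying genomic coordinates. When
#' coordinates are present, features are sorted by (chromosome, position) so
#' that sliding windows over adjacent probes are well defined.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param kind `"copy_number"` or `"methylation"`.
#' @param chrom,pos optional per-feature chromosome labels and 1-based
#'   positions (required for windowed methylation testing).
#' @return Object of class `genomic_matrix`.
#' @export
genomic_matrix <- function(values, kind = c("copy_number", "methylation"),
                           chrom = NULL, pos = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) .stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("'values' needs feature and sample names")
  coords <- NULL
  if (!is.null(chrom) || !is.null(pos)) {
    if (length(chrom) != nrow(values) || length(pos) != nrow(values))
      .stopf("chrom/pos must have one entry per feature")
    ord <- order(as.character(chrom), pos)
    values <- values[ord, , drop = FALSE]
    coords <- data.frame(chrom = as.character(chrom)[ord], pos = pos[ord],
                         row.names = rownames(values))
  }
  structure(list(values = values, kind = kind, coords = coords),
            class = "genomic_matrix")
}

#' @export
print.genomic_matrix <- function(x, ...) {
  cat(sprintf("genomic_matrix (%s): %d features x %d samples%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (!is.null(x$coords)) ", with coordinates" else ""))
  invisible(x)
}

#' Define extreme activity subgroups for a pathway pair
#'
#' Splits samples into the two opposed extreme groups used for genomic
#' correlate analyses: group 1 has high activity of pathway A and low activity
#' of pathway B; group 2 the reverse. Under the default symmetric rule, when
#' `cutoff >= 0.5` "high" means score > `cutoff` and "low" means score
#' `< 1 - cutoff`; when `cutoff < 0.5` the roles mirror (high > `1 - cutoff`,
#' low < `cutoff`), so the cutoff always names the stricter tail. With
#' `rule = "plain"` both conditions use the cutoff directly (high > cutoff,
#' low < cutoff). Samples meeting neither pattern are excluded.
#'
#' @param a an [activity_table()].
#' @param pathway_A,pathway_B pathway column names.
#' @param cutoff extremeness cutoff on the rescaled scores.
#' @param rule `"symmetric"` (default) or `"plain"`; see Details.
#' @return List with `group1` and `group2` sample-id vectors.
#' @export
define_extreme_groups <- function(a, pathway_A, pathway_B, cutoff = 0.5,
                                  rule = c("symmetric", "plain")) {
  stopifnot(inherits(a, "activity_table"))
  rule <- match.arg(rule)
  for (p in c(pathway_A, pathway_B))
    if (!p %in% a$pathways) .stopf("pathway '%s' not present", p)
  sA <- a$rescaled[, pathway_A]
  sB <- a$rescaled[, pathway_B]
  if (rule == "symmetric") {
    hi <- max(cutoff, 1 - cutoff)
    lo <- min(cutoff, 1 - cutoff)
  } else {
    hi <- cutoff; lo <- cutoff
  }
  g1 <- sA > hi & sB < lo
  g2 <- sA < lo & sB > hi
  if (!any(g1) || !any(g2))
    .stopf("empty extreme group (group1: %d, group2: %d samples)", sum(g1), sum(g2))
  list(group1 = a$sample_ids[g1], group2 = a$sample_ids[g2])
}

#' Subgroup-specific copy-number alteration filter
#'
#' A gene counts as altered within a subgroup when its copy-number log2
#' tumor/normal ratio exceeds `amp_threshold` (gain) or falls below
#' `del_threshold` (loss) in at least `min_fraction` of that subgroup's
#' samples. Genes altered, in either direction, in both subgroups are removed
#' as commonly altered; the remainder are labelled by the subgroup and
#' direction of their alteration, or `none`. A gene both gained and lost
#' within one subgroup is labelled by the more frequent direction.
#'
#' @param g a `genomic_matrix` of kind `"copy_number"`.
#' @param group1,group2 disjoint non-empty sample-id vectors.
#' @param amp_threshold,del_threshold log2-ratio thresholds (defaults 0.5 and
#'   -0.5).
#' @param min_fraction minimum altered fraction within a subgroup (default 0.2).
#' @return data.frame (one row per gene) with per-group gain/loss fractions
#'   and a `status` factor in `{group1_specific_gain, group1_specific_loss,
#'   group2_specific_gain, group2_specific_loss, removed, none}`.
#' @export
cnv_subgroup_filter <- function(g, group1, group2, amp_threshold = 0.5,
                                del_threshold = -0.5, min_fraction = 0.2) {
  stopifnot(inherits(g, "genomic_matrix"), g$kind == "copy_number")
  if (length(intersect(group1, group2))) .stopf("groups must be disjoint")
  if (!length(group1) || !length(group2)) .stopf("both groups must be non-empty")
  miss <- setdiff(c(group1, group2), colnames(g$values))
  if (length(miss)) .stopf("samples not in matrix: %s", paste(miss, collapse = ", "))
  v1 <- g$values[, group1, drop = FALSE]
  v2 <- g$values[, group2, drop = FALSE]
  gain1 <- rowMeans(v1 > amp_threshold); loss1 <- rowMeans(v1 < del_threshold)
  gain2 <- rowMeans(v2 > amp_threshold); loss2 <- rowMeans(v2 < del_threshold)
  alt1 <- gain1 >= min_fraction | loss1 >= min_fraction
  alt2 <- gain2 >= min_fraction | loss2 >= min_fraction
  status <- rep("none", nrow(g$values))
  status[alt1 & alt2] <- "removed"
  only1 <- alt1 & !alt2
  status[only1] <- ifelse(gain1[only1] >= loss1[only1],
                          "group1_specific_gain", "group1_specific_loss")
  only2 <- alt2 & !alt1
  status[only2] <- ifelse(gain2[only2] >= loss2[only2],
                          "group2_specific_gain", "group2_specific_loss")
  data.frame(gene = rownames(g$values),
             gain_frac_group1 = gain1, loss_frac_group1 = loss1,
             gain_frac_group2 = gain2, loss_frac_group2 = loss2,
             status = factor(status, levels = c("group1_specific_gain",
                                                "group1_specific_loss",
                                                "group2_specific_gain",
                                                "group2_specific_loss",
                                                "removed", "none")),
             row.names = NULL)
}

# internal: window-average each feature over the centered window of adjacent
# same-chromosome probes (truncated at chromosome ends); returns a matrix of
# the same shape as g$values.
.window_average <- function(g, window_size) {
  if (window_size %% 2 != 1 || window_size < 1)
    .stopf("window_size must be odd and >= 1")
  if (is.null(g$coords)) .stopf("genomic coordinates are required for windowing")
  if (window_size == 1) return(g$values)
  half <- (window_size - 1) / 2
  out <- g$values
  for (ch in unique(g$coords$chrom)) {
    rows <- which(g$coords$chrom == ch)
    k <- length(rows)
    if (window_size > k)
      .warnf("window (%d) larger than chromosome %s probe count (%d); truncated",
             window_size, ch, k)
    cs <- apply(g$values[rows, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, matrix(cs, nrow = k))
    i <- seq_len(k)
    lo <- pmax(1L, i - half); hi <- pmin(k, i + half)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  out
}

# internal: row-wise Welch two-sample t-test between column sets idx1/idx2
.welch_rows <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p <- ifelse(is.finite(t) & !is.na(df), 2 * pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  data.frame(t = t, df = df, p = p)
}

#' Sliding-window differential-methylation test
#'
#' For each probe, per sample, methylation is averaged over the centered
#' window of `window_size` adjacent probes on the same chromosome (truncated
#' at chromosome ends), and the two subgroups are compared by a Welch
#' two-sample t-test on the window means. Probes with `p < alpha` are flagged
#' as kept. With `window_size = 1` this reduces exactly to a per-probe Welch
#' test. No per-feature multiple-testing correction is applied; error control
#' is by permutation via [permutation_false_positive_rate()], with an optional
#' Benjamini-Hochberg column available through `fdr = TRUE`.
#'
#' @param g a `genomic_matrix` of kind `"methylation"` with coordinates.
#' @param group1,group2 sample-id vectors, each of size >= 2.
#' @param window_size odd number of adjacent probes per window (default 5).
#' @param alpha retention threshold on the p-value (default 0.1).
#' @param fdr if `TRUE`, add a Benjamini-Hochberg adjusted p-value column
#'   (not part of the core procedure).
#' @return data.frame with one row per probe: `feature`, `chrom`, `pos`, `t`,
#'   `df`, `p`, `kept`.
#' @export
sliding_window_meth_test <- function(g, group1, group2, window_size = 5,
                                     alpha = 0.1, fdr = FALSE) {
  stopifnot(inherits(g, "genomic_matrix"), g$kind == "methylation")
  if (length(group1) < 2 || length(group2) < 2)
    .stopf("each group needs at least 2 samples")
  w <- .window_average(g, window_size)
  idx1 <- match(group1, colnames(g$values))
  idx2 <- match(group2, colnames(g$values))
  if (anyNA(idx1) || anyNA(idx2)) .stopf("group sample(s) not found in matrix")
  res <- .welch_rows(w, idx1, idx2)
  out <- data.frame(feature = rownames(g$values),
                    chrom = g$coords$chrom, pos = g$coords$pos,
                    t = res$t, df = res$df, p = res$p,
                    kept = res$p < alpha, row.names = NULL)
  if (fdr) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Permutation estimate of the false-positive rate
#'
#' Shuffles the subgroup labels (preserving group sizes) `n_perm` times and,
#' for each shuffle, records the fraction of probes retained at `alpha` by the
#' sliding-window test. The mean retained fraction estimates the false-positive
#' rate of the windowed scan; the spread across shuffles is reported alongside
#' (window overlap correlates neighbouring probes, so the spread is wider than
#' an independent-test binomial would suggest).
#'
#' @inheritParams sliding_window_meth_test
#' @param n_perm number of label shuffles (default 100).
#' @param seed optional integer seed.
#' @return List with `mean_fpr`, `sd_fpr`, `se_mean`, and the per-shuffle
#'   fractions `fractions`.
#' @export
permutation_false_positive_rate <- function(g, group1, group2, window_size = 5,
                                            alpha = 0.1, n_perm = 100,
                                            seed = NULL) {
  stopifnot(inherits(g, "genomic_matrix"))
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  w <- .window_average(g, window_size)
  pool <- match(c(group1, group2), colnames(g$values))
  if (anyNA(pool)) .stopf("group sample(s) not found in matrix")
  n1 <- length(group1)
  fractions <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(pool)
    res <- .welch_rows(w, perm[seq_len(n1)], perm[-seq_len(n1)])
    mean(res$p < alpha)
  }, numeric(1))
  list(mean_fpr = mean(fractions), sd_fpr = sd(fractions),
       se_mean = sd(fractions) / sqrt(n_perm), fractions = fractions)
}
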