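#' Log2-transform linear intensities
#'
#' Applies `log2(max(value, floor))` to a linear-scale matrix. The floor keeps
#' near-zero intensities from producing large negative values; the default of 1
#' maps anything at or below background to 0 on MAS5-style intensity scales.
#'
#' @param m an `expr_matrix` on the linear scale.
#' @param floor positive lower clamp applied before the transform.
#' @return The transformed `expr_matrix`, flagged `scale = "log2"`.
#' @export
log2_transform <- function(m, floor = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "log2") .stopf("matrix is already on the log2 scale")
  if (!is.numeric(floor) || floor <= 0) .stopf("'floor' must be a positive number")
  m$values <- log2(pmax(m$values, floor))
  m$scale <- "log2"
  m
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto the common reference distribution given by
#' the mean of the column order statistics. Ties within a column receive the
#' mean of the reference quantiles they span. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param m an `expr_matrix` with at least two samples.
#' @return The normalized `expr_matrix`, flagged `quantile_normalized`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2) .stopf("quantile normalization needs at least 2 samples")
  dn <- dimnames(m$values)
  m$values <- as.matrix(limma::normalizeQuantiles(m$values, ties = TRUE))
  dimnames(m$values) <- dn
  m$quantile_normalized <- TRUE
  m
}

#' Filter uninformative probes
#'
#' Two-step probe filter applied before signature training: (1) drop probes
#' whose expression exceeds the dataset-wide `low_signal_quantile` intensity
#' threshold in fewer than `min_present_fraction` of samples ("present at low
#' levels"); (2) drop probes whose across-sample variance falls below the
#' `variance_quantile` of the per-probe variance distribution ("did not vary
#' across samples"). Setting all three thresholds to 0 is a no-op. Surviving
#' probes keep their original order.
#'
#' @param m an `expr_matrix` on the log2 scale.
#' @param low_signal_quantile,min_present_fraction,variance_quantile fractions
#'   in `[0, 1]`; defaults 0.25 each.
#' @return The filtered `expr_matrix`, with an attribute `filter_counts`
#'   (probes removed at each step).
#' @export
filter_probes <- function(m, low_signal_quantile = 0.25,
                          min_present_fraction = 0.25,
                          variance_quantile = 0.25) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") .stopf("filter_probes expects log2-scale data")
  v <- m$values
  thr <- quantile(v, low_signal_quantile, names = FALSE)
  present <- rowMeans(v > thr)
  keep1 <- present >= min_present_fraction
  n_low <- sum(!keep1)
  v <- v[keep1, , drop = FALSE]
  if (nrow(v) == 0)
    .stopf("all probes removed by the low-signal filter; relax the thresholds")
  vars <- apply(v, 1, var)
  keep2 <- vars >= quantile(vars, variance_quantile, names = FALSE)
  n_flat <- sum(!keep2)
  v <- v[keep2, , drop = FALSE]
  if (nrow(v) == 0)
    .stopf("all probes removed by the variance filter; relax the thresholds")
  m$values <- v
  attr(m, "filter_counts") <- c(low_signal = n_low, low_variance = n_flat)
  m
}

#' Remove degraded samples by the GAPDH 3'/5' ratio
#'
#' Samples whose GAPDH 3'-end to 5'-end control-probe intensity ratio is
#' strictly greater than `max_ratio` are considered RNA-degraded and removed.
#' A ratio of exactly `max_ratio` is kept. Samples lacking the control
#' intensities are retained with a warning rather than silently dropped.
#'
#' @param m an `expr_matrix` with `gapdh3` and `gapdh5` sample annotations
#'   (linear-scale intensities).
#' @param max_ratio removal threshold; default 3.
#' @return The filtered `expr_matrix` with attribute `removed_samples`.
#' @export
filter_degraded_samples <- function(m, max_ratio = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  g3 <- .get_annotation(m, "gapdh3")
  g5 <- .get_annotation(m, "gapdh5")
  ratio <- g3 / g5
  missing <- is.na(ratio)
  if (any(missing))
    .warnf("GAPDH control intensities missing for %d sample(s); retained unfiltered",
           sum(missing))
  drop <- !missing & ratio > max_ratio
  out <- .subset_samples(m, !drop)
  attr(out, "removed_samples") <- colnames(m$values)[drop]
  out
}

#' Adjust batch effects by per-batch centering
#'
#' Location(/scale) batch adjustment: per gene, within each batch, the batch
#' mean is subtracted (and for `"center-scale"` the values are divided by the
#' batch standard deviation), after which the gene's global mean is restored so
#' that batches become mean-aligned per gene without moving the overall level.
#' This is a deliberately simple, transparent stand-in for heavier batch
#' correction schemes; the per-gene global mean is preserved exactly under
#' `"center"`.
#'
#' @param m an `expr_matrix` with a `batch` annotation on every sample.
#' @param strategy `"center"` or `"center-scale"`.
#' @return The adjusted `expr_matrix`.
#' @export
adjust_batches <- function(m, strategy = c("center", "center-scale")) {
  stopifnot(inherits(m, "expr_matrix"))
  strategy <- match.arg(strategy)
  batch <- as.factor(.get_annotation(m, "batch"))
  if (anyNA(batch)) .stopf("every sample needs a batch label")
  sizes <- table(batch)
  if (strategy == "center-scale" && any(sizes < 2))
    .stopf("center-scale needs >= 2 samples per batch (singleton batch: %s)",
           paste(names(sizes)[sizes < 2], collapse = ", "))
  v <- m$values
  gmean <- rowMeans(v)
  for (b in levels(batch)) {
    idx <- which(batch == b)
    sub <- v[, idx, drop = FALSE]
    bm <- rowMeans(sub)
    sub <- sub - bm
    if (strategy == "center-scale") {
      bs <- apply(sub, 1, sd)
      bs[bs == 0] <- 1
      sub <- sub / bs
    }
    v[, idx] <- sub
  }
  m$values <- v + gmean
  m
}

#' Average replicate samples
#'
#' Collapses replicate samples to their arithmetic mean, one column (or row,
#' for an activity table) per replicate group. Groups of size one pass through
#' unchanged. For activity tables the averaging is applied to the raw
#' probabilities and the dataset rescaling is recomputed afterwards, matching
#' the pipeline order predict, then average, then rescale.
#'
#' @param x an `expr_matrix` or an [activity_table()].
#' @param replicate_key name of the annotation holding the replicate-group key
#'   (for `expr_matrix`), or a vector of group keys aligned with samples.
#' @return An object of the same class with one sample per replicate group.
#' @export
average_replicates <- function(x, replicate_key = "replicate") {
  UseMethod("average_replicates")
}

# internal: resolve group keys for n samples
.replicate_groups <- function(replicate_key, m, n) {
  key <- if (length(replicate_key) == 1 && is.character(replicate_key) && !is.null(m))
    .get_annotation(m, replicate_key) else replicate_key
  key <- as.character(key)
  if (length(key) != n) .stopf("replicate key length %d != %d samples", length(key), n)
  if (anyNA(key) || any(!nzchar(key))) .stopf("empty replicate-group key")
  key
}

#' @export
average_replicates.expr_matrix <- function(x, replicate_key = "replicate") {
  key <- .replicate_groups(replicate_key, x, ncol(x$values))
  groups <- unique(key)
  v <- vapply(groups, function(g) rowMeans(x$values[, key == g, drop = FALSE]),
              numeric(nrow(x$values)))
  v <- matrix(v, nrow = nrow(x$values), dimnames = list(rownames(x$values), groups))
  ann <- NULL
  if (!is.null(x$annotations)) {
    ann <- x$annotations[match(groups, key), , drop = FALSE]
    rownames(ann) <- groups
  }
  expression_matrix(v, scale = x$scale, annotations = ann,
                    quantile_normalized = x$quantile_normalized)
}

#' @export
average_replicates.activity_table <- function(x, replicate_key) {
  key <- .replicate_groups(replicate_key, NULL, nrow(x$raw))
  groups <- unique(key)
  raw <- t(vapply(groups, function(g) colMeans(x$raw[key == g, , drop = FALSE]),
                  numeric(ncol(x$raw))))
  dimnames(raw) <- list(groups, colnames(x$raw))
  activity_table(raw, dataset_id = x$dataset_id)
}
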