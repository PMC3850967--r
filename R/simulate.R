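#' Simulate a two-class signature training set
#'
#' Generates a log2-scale expression matrix for a perturbation experiment:
#' per-probe baselines drawn from Normal(7, 1), Gaussian measurement noise of
#' SD `noise_sd` everywhere, and an additive shift of `effect_size * noise_sd`
#' on the signature genes of the activated-class samples. Optional additive
#' per-batch, per-probe offsets emulate processing batches. All randomness is
#' a pure function of `seed`.
#'
#' @param n_per_class samples per class (control and activated).
#' @param n_probes total probe count.
#' @param n_signature_genes number of probes carrying the class effect.
#' @param effect_size class shift in units of `noise_sd` (0 = null data).
#' @param batch_spec optional list `list(n_batches =, sd =)`; batches are
#'   assigned round-robin across samples and each batch adds a per-probe
#'   Normal(0, sd) offset.
#' @param noise_sd measurement noise SD (default 1).
#' @param seed integer seed (required: generators are pure functions of it).
#' @return List with `expression` (an [expression_matrix()], log2 scale, with
#'   `class` and optional `batch` annotations), `class` (0/1 vector), and
#'   `truth` (signature gene ids, effect size, baselines).
#' @export
simulate_training_set <- function(n_per_class = 10, n_probes = 1000,
                                  n_signature_genes = 200, effect_size = 2,
                                  batch_spec = NULL, noise_sd = 1, seed) {
  if (n_signature_genes > n_probes) .stopf("n_signature_genes exceeds n_probes")
  if (n_per_class < 2 || n_probes < 2) .stopf("invalid counts")
  set.seed(seed)
  n <- 2L * n_per_class
  probes <- sprintf("probe%05d", seq_len(n_probes))
  samples <- sprintf("S%03d", seq_len(n))
  cl <- rep(c(0L, 1L), each = n_per_class)
  baseline <- rnorm(n_probes, 7, 1)
  v <- baseline + matrix(rnorm(n_probes * n, 0, noise_sd), n_probes, n)
  sig <- sample(probes, n_signature_genes)
  v[match(sig, probes), cl == 1] <- v[match(sig, probes), cl == 1] +
    effect_size * noise_sd
  ann <- data.frame(class = cl, row.names = samples)
  if (!is.null(batch_spec)) {
    nb <- batch_spec$n_batches
    bsd <- if (is.null(batch_spec$sd)) 0.5 else batch_spec$sd
    batch <- rep_len(sprintf("batch%d", seq_len(nb)), n)
    off <- matrix(rnorm(n_probes * nb, 0, bsd), n_probes, nb)
    v <- v + off[, match(batch, sprintf("batch%d", seq_len(nb)))]
    ann$batch <- batch
  }
  dimnames(v) <- list(probes, samples)
  list(expression = expression_matrix(v, scale = "log2", annotations = ann),
       class = cl,
       truth = list(signature_genes = sort(sig), effect_size = effect_size,
                    noise_sd = noise_sd, baseline = setNames(baseline, probes)))
}

#' Simulate a tumor expression compendium with latent pathway activities
#'
#' Latent per-sample pathway activities are drawn from a Gaussian copula whose
#' Pearson parameter is adjusted from the target Spearman matrix by
#' `2 * sin(pi * rho_s / 6)`, then mapped to `[0, 1]` through the normal CDF.
#' Expression is `baseline + activity * effect * noise_sd` on each pathway's
#' signature genes plus Gaussian noise, so a fully active sample carries the
#' same shift as an activated training sample. Subtype labels are assigned by
#' `subtype_rule` applied to the latent activity matrix (default: the name of
#' the pathway with the highest latent activity).
#'
#' @param n_samples number of tumor samples.
#' @param pathway_spec named list, one entry per pathway, each a list with
#'   `genes` (character vector of probe ids) and `effect` (shift in noise-SD
#'   units for a fully active sample).
#' @param target_rank_correlation symmetric positive semi-definite Spearman
#'   correlation matrix (pathways x pathways, unit diagonal).
#' @param subtype_rule `NULL`, or a function `f(latent_matrix) -> labels`.
#' @param n_probes total probe count; probe ids are `probe00001`-style and
#'   must cover every id in `pathway_spec`.
#' @param noise_sd measurement noise SD.
#' @param seed integer seed.
#' @return List with `expression` (log2-scale [expression_matrix()] with a
#'   `subtype` annotation when a rule applies) and `truth` (latent activities,
#'   target correlations, gene sets, subtypes).
#' @export
simulate_tumor_compendium <- function(n_samples, pathway_spec,
                                      target_rank_correlation,
                                      subtype_rule = NULL, n_probes = 1000,
                                      noise_sd = 1, seed) {
  k <- length(pathway_spec)
  stopifnot(k >= 1, !is.null(names(pathway_spec)))
  rho <- as.matrix(target_rank_correlation)
  if (nrow(rho) != k || ncol(rho) != k) .stopf("correlation matrix must be %d x %d", k, k)
  if (max(abs(rho - t(rho))) > 1e-8 || any(abs(diag(rho) - 1) > 1e-8))
    .stopf("target correlation must be symmetric with unit diagonal")
  pearson <- 2 * sin(pi * rho / 6)
  ev <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    .stopf("adjusted correlation matrix is not positive semi-definite (eigenvalue %.3g)",
           min(ev))
  set.seed(seed)
  probes <- sprintf("probe%05d", seq_len(n_probes))
  for (p in names(pathway_spec)) {
    miss <- setdiff(pathway_spec[[p]]$genes, probes)
    if (length(miss)) .stopf("pathway '%s' names probes outside the matrix", p)
  }
  samples <- sprintf("T%04d", seq_len(n_samples))
  # Gaussian copula draw
  ch <- chol(pearson + diag(1e-10, k))
  z <- matrix(rnorm(n_samples * k), n_samples, k) %*% ch
  latent <- pnorm(z)
  colnames(latent) <- names(pathway_spec)
  rownames(latent) <- samples
  baseline <- rnorm(n_probes, 7, 1)
  v <- baseline + matrix(rnorm(n_probes * n_samples, 0, noise_sd), n_probes, n_samples)
  for (p in names(pathway_spec)) {
    gi <- match(pathway_spec[[p]]$genes, probes)
    eff <- pathway_spec[[p]]$effect
    v[gi, ] <- v[gi, ] + matrix(latent[, p] * eff * noise_sd,
                                length(gi), n_samples, byrow = TRUE)
  }
  dimnames(v) <- list(probes, samples)
  subtypes <- NULL
  if (is.null(subtype_rule) && k > 1)
    subtype_rule <- function(l) colnames(l)[max.col(l, ties.method = "first")]
  ann <- NULL
  if (!is.null(subtype_rule)) {
    subtypes <- subtype_rule(latent)
    ann <- data.frame(subtype = as.character(subtypes), row.names = samples)
  }
  list(expression = expression_matrix(v, scale = "log2", annotations = ann),
       truth = list(latent_activity = latent, target_rank_correlation = rho,
                    gene_sets = lapply(pathway_spec, `[[`, "genes"),
                    subtypes = subtypes))
}

#' Simulate activity scores with exact quadrant probabilities
#'
#' Complement to the copula compendium for exact-count testing of quadrant
#' classification: each sample's quadrant is drawn from the given multinomial
#' probabilities and a pair of rescaled-style scores consistent with that
#' quadrant (uniform on the admissible side of the threshold) is emitted.
#'
#' @param n number of samples.
#' @param probs length-4 numeric vector of quadrant probabilities in the order
#'   both, A_only, B_only, neither; must sum to 1.
#' @param threshold activation threshold the scores straddle (default 0.5).
#' @param seed integer seed.
#' @return List with `scores` (n x 2 matrix, columns `A` and `B`) and
#'   `quadrant` (factor of planted labels).
#' @export
simulate_quadrant_scores <- function(n, probs, threshold = 0.5, seed) {
  if (length(probs) != 4 || abs(sum(probs) - 1) > 1e-8 || any(probs < 0))
    .stopf("probs must be 4 non-negative values summing to 1")
  set.seed(seed)
  lab <- sample(c("both", "A_only", "B_only", "neither"), n, TRUE, probs)
  hi <- function(m) threshold + runif(m) * (1 - threshold)
  lo <- function(m) runif(m) * threshold
  a <- ifelse(lab %in% c("both", "A_only"), hi(n), lo(n))
  b <- ifelse(lab %in% c("both", "B_only"), hi(n), lo(n))
  scores <- cbind(A = a, B = b)
  rownames(scores) <- sprintf("S%05d", seq_len(n))
  list(scores = scores, quadrant = factor(lab, c("both", "A_only", "B_only", "neither")))
}

#' Simulate copy-number and methylation correlates for two subgroups
#'
#' Copy-number log2 tumor/normal ratios are Normal(0, 0.15^2) background with
#' planted subgroup-specific gains (+0.8) or losses (-0.8) affecting a given
#' fraction of the target subgroup's samples. Methylation values are
#' Beta(2, 2) background with planted additive window shifts for one
#' subgroup, clipped to (0.01, 0.99). Features are laid out on two synthetic
#' chromosomes with evenly spaced coordinates.
#'
#' @param group1,group2 sample-id vectors (disjoint); the matrices cover their
#'   union.
#' @param n_genes copy-number genes.
#' @param n_probes methylation probes.
#' @param planted_cnv list of lists `list(gene = index, group = 1 or 2,
#'   direction = "gain"/"loss", fraction = )`.
#' @param planted_meth list of lists `list(probes = indices, group = 1 or 2,
#'   shift = )`.
#' @param seed integer seed.
#' @return List with `copy_number` and `methylation` [genomic_matrix()]
#'   objects and `truth` echoing the planted effects.
#' @export
simulate_genomic_correlates <- function(group1, group2, n_genes = 500,
                                        n_probes = 1000, planted_cnv = list(),
                                        planted_meth = list(), seed) {
  if (length(intersect(group1, group2))) .stopf("groups must be disjoint")
  set.seed(seed)
  samples <- c(group1, group2)
  n <- length(samples)
  groups <- list(group1, group2)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  cnv <- matrix(rnorm(n_genes * n, 0, 0.15), n_genes, n,
                dimnames = list(genes, samples))
  for (pl in planted_cnv) {
    if (pl$fraction > 1) .stopf("planted fraction > 1")
    gs <- groups[[pl$group]]
    hit <- sample(gs, max(1, round(pl$fraction * length(gs))))
    cnv[pl$gene, hit] <- cnv[pl$gene, hit] + if (pl$direction == "gain") 0.8 else -0.8
  }
  probes <- sprintf("cg%05d", seq_len(n_probes))
  meth <- matrix(rbeta(n_probes * n, 2, 2), n_probes, n,
                 dimnames = list(probes, samples))
  for (pl in planted_meth) {
    gs <- groups[[pl$group]]
    meth[pl$probes, gs] <- pmin(0.99, pmax(0.01, meth[pl$probes, gs] + pl$shift))
  }
  half_g <- ceiling(n_genes / 2); half_p <- ceiling(n_probes / 2)
  gchrom <- rep(c("chr1", "chr2"), c(half_g, n_genes - half_g))
  gpos <- c(seq_len(half_g), seq_len(n_genes - half_g)) * 1000L
  pchrom <- rep(c("chr1", "chr2"), c(half_p, n_probes - half_p))
  ppos <- c(seq_len(half_p), seq_len(n_probes - half_p)) * 500L
  list(copy_number = genomic_matrix(cnv, "copy_number", gchrom, gpos),
       methylation = genomic_matrix(meth, "methylation", pchrom, ppos),
       truth = list(planted_cnv = planted_cnv, planted_meth = planted_meth))
}
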