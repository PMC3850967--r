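#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with every
#' stage's parameters exposed and a single master seed from which each
#' stochastic stage derives its own sub-seed (so stages stay reproducible
#' independently of which subset runs).
#'
#' @param seed master integer seed (required; every stochastic stage derives
#'   from it).
#' @param output_dir directory for artifacts.
#' @return Named configuration list.
#' @export
default_config <- function(seed, output_dir = tempfile("pathsig_run_")) {
  if (missing(seed) || is.null(seed)) .stopf("a master seed is required")
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    simulate = list(n_per_class = 10, n_probes = 1000, n_signature_genes = 200,
                    effect_size = 2, noise_sd = 1,
                    n_tumors = 500, pathways = c("EZH2", "HDAC4"),
                    genes_per_pathway = 100, rho_s = -0.7),
    train = list(n_genes = 200, n_draws = 2000, burn_in = 500),
    loocv = list(enabled = FALSE, n_draws = 1000, burn_in = 200),
    exclusivity = list(threshold = 0.5),
    correlates = list(enabled = TRUE, cutoff = 0.5, window_size = 5,
                      alpha = 0.1, n_perm = 50,
                      n_genes = 300, n_probes = 400))
}

# internal: derive a stage sub-seed from the master seed (kept < 2^31)
.stage_seed <- function(seed, offset) (as.integer(seed) * 1009L + offset) %% 2147483647L

# internal: polynomial rolling hash of the serialized config, for provenance
# stamping in the run log (not cryptographic)
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# internal: write a numeric matrix as a TSV with shortest-round-trip values
.write_matrix_tsv <- function(x, path, id_col = "id") {
  ids <- if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
  txt <- matrix(sprintf("%.17g", x), nrow(x), dimnames = list(NULL, colnames(x)))
  out <- cbind(setNames(data.frame(ids), id_col), txt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pathway-signature pipeline
#'
#' Orchestrates the stages end to end on synthetic data with known ground
#' truth: simulate training set and tumor compendium, preprocess (quantile
#' normalization), train one signature per pathway, optional LOOCV, project
#' onto the compendium, rescale, exclusivity analysis (Spearman correlations,
#' quadrant classification, co-activation deficit test), and genomic
#' correlates (extreme groups, planted copy-number filter, sliding-window
#' methylation scan with permutation calibration). Every artifact is written
#' as TSV/JSON under `config$output_dir`; rerunning with the same config
#' reproduces all numeric artifacts bitwise.
#'
#' @param config configuration list from [default_config()].
#' @param stages ordered subset of
#'   `c("simulate", "train", "loocv", "predict", "exclusivity", "correlates")`.
#' @return Invisibly, a list of in-memory results per stage; artifacts on disk.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "train", "predict",
                                    "exclusivity", "correlates")) {
  if (is.null(config$seed)) .stopf("config validation: missing master seed")
  stages <- match.arg(stages, c("simulate", "train", "loocv", "predict",
                                "exclusivity", "correlates"), several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config_hash = .config_hash(config), stages = stages,
              timings = list())
  res <- list()
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    list(out = out, secs = round(proc.time()[["elapsed"]] - t0, 3))
  }

  if ("simulate" %in% stages) {
    sc <- config$simulate
    st <- t_stage({
      train_sets <- lapply(seq_along(sc$pathways), function(i)
        simulate_training_set(sc$n_per_class, sc$n_probes, sc$n_signature_genes,
                              sc$effect_size, noise_sd = sc$noise_sd,
                              seed = .stage_seed(config$seed, i)))
      names(train_sets) <- sc$pathways
      k <- length(sc$pathways)
      rho <- diag(k)
      if (k >= 2) rho[1, 2] <- rho[2, 1] <- sc$rho_s
      spec <- list()
      for (i in seq_len(k)) {
        genes <- train_sets[[i]]$truth$signature_genes
        spec[[sc$pathways[i]]] <- list(genes = genes[seq_len(min(sc$genes_per_pathway,
                                                                 length(genes)))],
                                       effect = sc$effect_size)
      }
      compendium <- simulate_tumor_compendium(sc$n_tumors, spec, rho,
                                              n_probes = sc$n_probes,
                                              noise_sd = sc$noise_sd,
                                              seed = .stage_seed(config$seed, 100L))
      list(train_sets = train_sets, compendium = compendium)
    })
    res$simulate <- st$out
    log$timings$simulate <- st$secs
    .write_matrix_tsv(res$simulate$compendium$truth$latent_activity,
                      file.path(config$output_dir, "latent_activity.tsv"),
                      "sample_id")
  }

  if ("train" %in% stages) {
    if (is.null(res$simulate)) .stopf("stage 'train' failed: no training data (run simulate)")
    tc <- config$train
    st <- t_stage(lapply(seq_along(res$simulate$train_sets), function(i) {
      ts <- res$simulate$train_sets[[i]]
      m <- quantile_normalize(ts$expression)
      train_signature(m, ts$class, n_genes = tc$n_genes, n_draws = tc$n_draws,
                      burn_in = tc$burn_in, seed = .stage_seed(config$seed, 200L + i),
                      pathway = names(res$simulate$train_sets)[i])
    }))
    res$models <- setNames(st$out, names(res$simulate$train_sets))
    log$timings$train <- st$secs
    for (p in names(res$models))
      .write_matrix_tsv(res$models[[p]]$draws,
                        file.path(config$output_dir, paste0("posterior_", p, ".tsv")),
                        "draw")
  }

  if ("loocv" %in% stages) {
    if (is.null(res$simulate)) .stopf("stage 'loocv' failed: no training data")
    lc <- config$loocv
    st <- t_stage(lapply(seq_along(res$simulate$train_sets), function(i) {
      ts <- res$simulate$train_sets[[i]]
      m <- quantile_normalize(ts$expression)
      run_loocv(m, ts$class, n_genes = config$train$n_genes,
                n_draws = lc$n_draws, burn_in = lc$burn_in,
                seed = .stage_seed(config$seed, 300L + i))
    }))
    res$loocv <- setNames(st$out, names(res$simulate$train_sets))
    log$timings$loocv <- st$secs
    log$loocv_accuracy <- lapply(res$loocv, `[[`, "accuracy")
  }

  if ("predict" %in% stages) {
    if (is.null(res$models)) .stopf("stage 'predict' failed: no trained models")
    st <- t_stage({
      target <- quantile_normalize(res$simulate$compendium$expression)
      predict_activity(res$models, target, dataset_id = "synthetic_compendium")
    })
    res$activity <- st$out
    log$timings$predict <- st$secs
    write_activity_table(res$activity, file.path(config$output_dir, "activity.tsv"))
  }

  if ("exclusivity" %in% stages) {
    if (is.null(res$activity)) .stopf("stage 'exclusivity' failed: no activity table")
    ec <- config$exclusivity
    st <- t_stage({
      corr <- pairwise_correlations(res$activity)
      pw <- res$activity$pathways
      quad <- if (length(pw) >= 2)
        classify_quadrants(res$activity, pw[1], pw[2], ec$threshold) else NULL
      list(correlations = corr, quadrants = quad)
    })
    res$exclusivity <- st$out
    log$timings$exclusivity <- st$secs
    .write_matrix_tsv(res$exclusivity$correlations$r,
                      file.path(config$output_dir, "spearman_r.tsv"), "pathway")
    if (!is.null(res$exclusivity$quadrants)) {
      qs <- res$exclusivity$quadrants$summary
      log$quadrants <- list(counts = as.list(qs$counts),
                            observed = qs$observed_coactivation,
                            expected = qs$expected_coactivation,
                            p_value = qs$p_value)
    }
  }

  if ("correlates" %in% stages && isTRUE(config$correlates$enabled)) {
    if (is.null(res$activity)) .stopf("stage 'correlates' failed: no activity table")
    cc <- config$correlates
    st <- t_stage({
      pw <- res$activity$pathways
      groups <- define_extreme_groups(res$activity, pw[1], pw[2], cc$cutoff)
      gm <- simulate_genomic_correlates(
        groups$group1, groups$group2, n_genes = cc$n_genes, n_probes = cc$n_probes,
        planted_cnv = list(list(gene = 1, group = 1, direction = "gain", fraction = 0.4)),
        planted_meth = list(list(probes = 1:5, group = 1, shift = 0.3)),
        seed = .stage_seed(config$seed, 400L))
      cnv <- cnv_subgroup_filter(gm$copy_number, groups$group1, groups$group2)
      meth <- sliding_window_meth_test(gm$methylation, groups$group1, groups$group2,
                                       cc$window_size, cc$alpha)
      fpr <- permutation_false_positive_rate(gm$methylation, groups$group1,
                                             groups$group2, cc$window_size,
                                             cc$alpha, cc$n_perm,
                                             seed = .stage_seed(config$seed, 401L))
      list(groups = groups, cnv = cnv, methylation = meth, fpr = fpr)
    })
    res$correlates <- st$out
    log$timings$correlates <- st$secs
    write.table(res$correlates$cnv, file.path(config$output_dir, "cnv_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mtab <- res$correlates$methylation
    mtab$t <- sprintf("%.17g", mtab$t); mtab$p <- sprintf("%.17g", mtab$p)
    mtab$df <- sprintf("%.17g", mtab$df)
    write.table(mtab, file.path(config$output_dir, "methylation_test.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log$correlates <- list(group_sizes = lengths(res$correlates$groups),
                           mean_fpr = res$correlates$fpr$mean_fpr)
  }

  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
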