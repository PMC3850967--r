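test_that("gene selection finds a strongly shifted probe and ranks exhaustively", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    v <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
    cl <- rep(c(0, 1), each = 6)
    v["g07", cl == 1] <- v["g07", cl == 1] + 5   # 5-SD shift on one probe
    sel <- select_signature_genes(toy_expr(v), cl, n_genes = 1)
    if (sel == "g07") hits <- hits + 1L
  }
  expect_gte(hits, 99L)
  # exhaustive selection returns all probes ordered by |statistic|
  set.seed(2)
  v <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  cl <- rep(c(0, 1), each = 5)
  sel <- select_signature_genes(toy_expr(v), cl, n_genes = 20)
  expect_setequal(sel, rownames(v))
  stat <- attr(sel, "statistic")
  expect_true(all(diff(abs(stat)) <= 1e-12))
  expect_error(select_signature_genes(toy_expr(v), cl, n_genes = 21), "between")
  expect_error(select_signature_genes(toy_expr(v), c(rep(0, 9), 1), 5), "2 samples")
})

test_that("no probe dominates selection under permuted null labels", {
  set.seed(31)
  v <- matrix(rnorm(1000 * 16), 1000, 16,
              dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:16)))
  m <- toy_expr(v)
  counts <- integer(1000)
  names(counts) <- rownames(v)
  for (i in 1:200) {
    cl <- sample(rep(c(0, 1), each = 8))
    sel <- select_signature_genes(m, cl, n_genes = 20)
    counts[sel] <- counts[sel] + 1L
  }
  expect_lt(max(counts) / 200, 0.5)
})

test_that("the SVD metagene recovers rank-1 structure with class-aware orientation", {
  # rank-1 construction: class-1 columns +c*u0, class-0 columns -c*u0 (after
  # per-gene standardization the structure is preserved up to gene scaling)
  u0 <- c(0.6, -0.8, 0.0, 0.0)
  v <- cbind(-2 * u0, -1.5 * u0, -1.8 * u0, 2 * u0, 1.5 * u0, 1.8 * u0)
  v <- v + c(5, 6, 0, 0)            # gene means; two genes are flat
  dimnames(v) <- list(c("a", "b", "c", "d"), sprintf("s%d", 1:6))
  cl <- rep(c(0, 1), each = 3)
  expect_error(compute_metagene(v, cl), "zero-variance")
  v <- v[1:2, , drop = FALSE] + matrix(rnorm(12, 0, 1e-8), 2)
  mg <- compute_metagene(v, cl)
  expect_equal(sqrt(sum(mg$u^2)), 1, tolerance = 1e-12)
  expect_gt(mg$d, 0)
  # orientation: class-1 scores higher on average, here strictly positive
  expect_true(all(mg$scores[cl == 1] > 0))
  expect_gte(mean(mg$scores[cl == 1]), mean(mg$scores[cl == 0]))
  # scores equal u' x for standardized profiles (algebraic identity)
  x <- (v - rowMeans(v)) / apply(v, 1, sd)
  expect_equal(unname(drop(crossprod(x, mg$u))), unname(mg$scores), tolerance = 1e-8)
})

test_that("metagene scores are invariant to a global expression scaling", {
  set.seed(5)
  v <- matrix(rnorm(30 * 10, 7), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  cl <- rep(c(0, 1), each = 5)
  v[1:5, cl == 1] <- v[1:5, cl == 1] + 2
  sel1 <- select_signature_genes(toy_expr(v), cl, 10)
  sel2 <- select_signature_genes(toy_expr(v * 3), cl, 10)
  expect_identical(as.character(sel1), as.character(sel2))
  mg1 <- compute_metagene(v[sel1, ], cl)
  mg2 <- compute_metagene((v * 3)[sel1, ], cl)
  expect_equal(mg1$scores, mg2$scores, tolerance = 1e-9)
})

test_that("the Gibbs probit sampler matches the quadrature oracle and is deterministic", {
  toy <- probit_toy()
  d1 <- fit_probit_bayes(toy$scores, toy$y, n_draws = 4000, burn_in = 500, seed = 9)
  d2 <- fit_probit_bayes(toy$scores, toy$y, n_draws = 4000, burn_in = 500, seed = 9)
  expect_identical(d1, d2)
  oracle <- probit_quadrature_means(toy$scores, toy$y, n_grid = 201)
  expect_lt(abs(mean(d1[, "alpha"]) - oracle["alpha"]), 0.05)
  expect_lt(abs(mean(d1[, "beta"]) - oracle["beta"]), 0.05)
  expect_error(fit_probit_bayes(c(1, NA, 2), c(0, 1, 1)), "non-finite")
  expect_error(fit_probit_bayes(c(1, 2), c(0, 1), prior_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("posterior alpha is centred near zero for symmetric overlapping data", {
  # symmetric scores with symmetric label noise: posterior of alpha symmetric
  scores <- rep(c(-1, -0.5, 0.5, 1), each = 5)
  y <- c(rep(0, 4), 1, rep(0, 4), 1, 0, rep(1, 4), 0, rep(1, 4))
  d <- fit_probit_bayes(scores, y, n_draws = 20000, burn_in = 2000, seed = 13)
  mc_se <- sd(d[, "alpha"]) / sqrt(nrow(d) / 20)  # conservative ESS guess
  expect_lt(abs(mean(d[, "alpha"])), max(4 * mc_se, 0.1))
})

test_that("training on separated classes yields confident, reproducible fits", {
  sim <- simulate_training_set(n_per_class = 10, n_probes = 400,
                               n_signature_genes = 80, effect_size = 2, seed = 71)
  m <- quantile_normalize(sim$expression)
  fit <- train_signature(m, sim$class, n_genes = 80, n_draws = 1500,
                         burn_in = 300, seed = 5)
  expect_s3_class(fit, "pathway_signature")
  expect_true(all(fit$fitted_prob[sim$class == 1] > 0.5))
  expect_true(all(fit$fitted_prob[sim$class == 0] < 0.5))
  # with positive beta mass, fitted probability is monotone in the score
  ord <- order(fit$train_scores)
  expect_true(all(diff(fit$fitted_prob[ord]) >= -1e-12))
  # serialization round-trip reproduces predictions exactly
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, path)
  fit2 <- readRDS(path)
  expect_identical(predict(fit2, m), predict(fit, m))
  # class labels may come from an annotation column
  m$annotations <- data.frame(class = sim$class, row.names = colnames(m$values))
  fit3 <- train_signature(m, "class", n_genes = 80, n_draws = 200,
                          burn_in = 50, seed = 5)
  expect_identical(fit3$gene_ids, fit$gene_ids)
})

test_that("shuffled labels give near-chance training probabilities", {
  sim <- simulate_training_set(n_per_class = 10, n_probes = 300,
                               n_signature_genes = 60, effect_size = 2, seed = 72)
  m <- quantile_normalize(sim$expression)
  set.seed(40)
  mean_probs <- vapply(1:50, function(i) {
    cl <- sample(sim$class)
    fit <- train_signature(m, cl, n_genes = 60, n_draws = 400, burn_in = 100)
    mean(fit$fitted_prob)
  }, numeric(1))
  expect_lt(abs(mean(mean_probs) - 0.5), 0.1)
})

test_that("LOOCV produces one held-out prediction per sample and separates cleanly", {
  sim <- simulate_training_set(n_per_class = 8, n_probes = 300,
                               n_signature_genes = 60, effect_size = 2, seed = 73)
  m <- quantile_normalize(sim$expression)
  cv <- run_loocv(m, sim$class, n_genes = 60, n_draws = 600, burn_in = 150, seed = 3)
  expect_length(cv$probabilities, 16L)
  expect_equal(sum(cv$confusion), 16)
  expect_equal(cv$accuracy, 1.0)
  expect_error(run_loocv(m, c(rep(0, 14), 1, 1)), "3 samples")
})
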