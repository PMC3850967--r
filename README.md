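# pathsig

Bayesian probit pathway-activity signatures for tumor expression compendia,
with mutual-exclusivity and genomic-correlate analysis.

## What it is for

Epigenetic regulators — EZH2, HDAC1, HDAC4, SIRT1, DNMT2 — shape cancer
phenotypes through the transcriptional programs they drive, not through
recurrent mutations that could be read off a genome. `pathsig` is for
computational biologists who want to estimate how active such a pathway is in
each of thousands of tumors using expression data alone, starting from a
small controlled experiment (cells with the pathway activated versus matched
controls), and then ask population-scale questions: which pathways are
mutually exclusive, which tumor subtypes are enriched for high activation,
and what copy-number or methylation changes distinguish activity-defined
tumor subgroups.

## The model

Given a two-class training matrix, the package

1. selects the `n` probes with the largest regularized signal-to-noise
   statistic (x̄₁ − x̄₀)/(s_pooled + s₀);
2. summarizes them as a **metagene**: the first singular vector *u* of the
   standardized genes × samples matrix, giving each sample the score
   *m_j = uᵀx_j*;
3. fits a **Bayesian binary probit regression** P(y_j = 1) = Φ(α + β m_j) by
   the Albert–Chib data-augmentation Gibbs sampler under a N(0, 100·I)
   prior, and validates the signature by full leave-one-out cross-validation
   (gene selection re-run in every fold).

Projection onto a new dataset standardizes the matched signature genes within
that dataset, applies the fixed loading *u*, and reports the posterior-mean
probability (1/T)·Σ_t Φ(α_t + β_t m_j). For cross-dataset comparison,
probabilities are log-transformed and min–max rescaled to [0, 1] within each
dataset.

Downstream, `pairwise_correlations()`, `classify_quadrants()` and
`coactivation_deficit_test()` quantify exclusivity (the deficit test is a
one-sided Fisher exact test by default), `subtype_association()` runs the
ANOVA and enrichment summaries, and `define_extreme_groups()`,
`cnv_subgroup_filter()`, `sliding_window_meth_test()` and
`permutation_false_positive_rate()` link activity subgroups to copy-number
and methylation changes. A synthetic-data module
(`simulate_training_set()`, `simulate_tumor_compendium()`,
`simulate_genomic_correlates()`) generates every input with known ground
truth.

## Worked example

Train two signatures on simulated perturbation experiments, project them onto
a 2,000-tumor synthetic compendium whose latent EZH2/HDAC4 activities have
Spearman correlation −0.7, and test for mutual exclusivity:

```r
library(pathsig)

sim <- simulate_training_set(n_per_class = 10, n_probes = 1000,
                             n_signature_genes = 200, effect_size = 2, seed = 7)
train <- quantile_normalize(sim$expression)
fit <- train_signature(train, sim$class, n_genes = 200,
                       n_draws = 2000, burn_in = 500, seed = 8,
                       pathway = "EZH2")
fit
#> Pathway signature 'EZH2'
#>   200 signature genes; metagene singular value d = 40.827
#>   probit posterior means: alpha = 2.153, beta = 3.496 (2000 draws)
#>   training: 10 control / 10 activated samples

run_loocv(train, sim$class, n_genes = 200, n_draws = 1000,
          burn_in = 200, seed = 9)$accuracy
#> [1] 1

ts2 <- simulate_training_set(10, 1000, 200, 2, seed = 17)
fit2 <- train_signature(quantile_normalize(ts2$expression), ts2$class,
                        n_genes = 200, n_draws = 2000, burn_in = 500,
                        seed = 18, pathway = "HDAC4")

spec <- list(EZH2  = list(genes = sim$truth$signature_genes, effect = 2),
             HDAC4 = list(genes = ts2$truth$signature_genes, effect = 2))
comp <- simulate_tumor_compendium(2000, spec,
                                  matrix(c(1, -0.7, -0.7, 1), 2),
                                  n_probes = 1000, seed = 19)
act <- predict_activity(list(EZH2 = fit, HDAC4 = fit2),
                        quantile_normalize(comp$expression))

pairwise_correlations(act)$r
#>             EZH2      HDAC4
#> EZH2   1.0000000 -0.7389525
#> HDAC4 -0.7389525  1.0000000

classify_quadrants(act, "EZH2", "HDAC4")$summary
#> Quadrant summary: EZH2 vs HDAC4 (threshold 0.5, n = 2000)
#>    both  A_only  B_only neither
#>    1553     155     292       0
#> observed co-activation 0.7765 vs expected 0.7878 (marginals 0.8540, 0.9225)
#> co-activation deficit p = 8.062e-12
```

The signature recovers the planted truth: LOOCV separates the training
classes perfectly; the projected activities reproduce the planted negative
dependence (Spearman −0.74 against a latent target of −0.7, and rank
correlation 0.98 between each pathway's rescaled score and its latent
activity); and the quadrant analysis shows fewer co-activated tumors than
independent activation at the observed marginals would produce, with the
Fisher deficit test rejecting decisively. Note that absolute activation
fractions on synthetic compendia are high by construction — see the vignette
(`vignettes/pathway-signatures.Rmd`) for why, and for everything the
generator does and does not emulate.

`run_pipeline(default_config(seed = 1))` runs the whole chain — simulate,
train, project, exclusivity, genomic correlates — and writes TSV/JSON
artifacts that are bitwise reproducible for a fixed config.

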