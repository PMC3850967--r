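---
title: "Pathway-activity signatures: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-activity signatures: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsig)
```

## The problem

Epigenetic regulators (histone deacetylases such as HDAC1/HDAC4, the histone
methylase EZH2, the sirtuin SIRT1, the methyltransferase DNMT2) are rarely
mutated in cancer in ways that flag their activity directly; what changes is
the downstream transcriptional program. `pathsig` estimates per-tumor
*pathway activity* from expression data alone: a signature is trained on a
controlled two-class experiment (cells with the pathway experimentally
activated versus matched controls) and then projected onto tumor compendia,
where relationships among pathway activities — mutual exclusivity,
subtype association, copy-number and methylation correlates — can be
quantified.

## The model

**Gene selection.** Probes are ranked by a regularized signal-to-noise
statistic $(\bar x_1 - \bar x_0) / (s_{\text{pooled}} + s_0)$, with the
stabilizer $s_0$ set to the median pooled SD across probes so that
low-variance probes cannot dominate through tiny denominators. The top
`n_genes` (default 200) form the signature. Ties are broken lexicographically
by probe id so that selection is deterministic.

**Metagene.** The selected genes are standardized (mean 0, SD 1 per gene
across training samples) and decomposed by SVD. The first left singular
vector $u$ (unit length) is the metagene loading; sample $j$'s metagene score
is $m_j = u^\top x_j$, identically $d\,v_{1j}$. The sign is oriented so the
activated class has the higher mean score. A single metagene is used; the
`n_metagenes` config slot is reserved should multiple components ever be
wanted.

**Probit regression.** Class membership is modelled as
$P(y_j = 1) = \Phi(\alpha + \beta m_j)$ with a weakly informative
$N(0, 100 I)$ prior on $(\alpha, \beta)$. The posterior is sampled by the
standard data-augmentation Gibbs scheme (truncated-normal latent variables,
conjugate normal update), implemented in compiled code but driven by R's RNG,
so a seed makes every chain exactly reproducible. Defaults are 5,000 retained
draws after 1,000 burn-in; repeated-fit settings (cross-validation,
simulation studies, the acceptance script) use 400–2,000 draws, which we
verified leaves 0.5-threshold classifications unchanged on the problem sizes
used here.

**Prediction.** A sample's activation probability is the posterior mean
$\frac{1}{T}\sum_t \Phi(\alpha_t + \beta_t m_j)$, *not* $\Phi$ at the
posterior-mean coefficients — with heavy-tailed posteriors the two differ
materially, and the posterior-mean probability honestly propagates coefficient
uncertainty. Probabilities are clamped to $[10^{-15}, 1 - 10^{-15}]$ because
$\Phi$ underflows to exactly 0/1 in double precision for $|\eta| \gtrsim 38$,
which would break the downstream log-rescaling.

**Rescaling.** For cross-dataset comparison, probabilities are
log-transformed and min–max scaled to $[0, 1]$ within each dataset. The log
base is immaterial (any base gives identical scores). An all-equal input is
degenerate and maps to 0.5, flagged on the result.

## Validation by cross-validation

`run_loocv()` repeats the *entire* fit — gene selection, metagene, probit —
with each sample held out in turn, predicting it from the training-fold
standardization parameters (within-dataset standardization being impossible
for a single sample). On separable synthetic data (2-SD effects, 10 per
class, 200 signature genes) accuracy is 1.0 across seeds; on null data it
fluctuates around 0.5, and slightly below on small samples because gene
selection overfits the training fold's noise, biasing held-out predictions
toward the wrong class — a known property of full-pipeline cross-validation,
not a defect.

## Projection across datasets

Signature genes are matched by shared identifiers; the loading vector is
restricted to matched genes and re-normalized, with an error below 50%
coverage. Target genes are standardized *within the target dataset* by
default: after quantile normalization this is the only scale-robust choice
when projecting across platforms. Standardization with the training
parameters is available (`standardize = "training"`) for same-platform use.
The training basis is held fixed (no joint train+target SVD): projection is
stateless and reproducible. The pipeline order is fixed as predict, then
average replicates (on raw probabilities), then rescale — averaging and
rescaling do not commute, and replicate averaging belongs on the probability
scale.

## Exclusivity statistics

Pairwise Spearman correlations use average ranks with the large-sample t
approximation for p-values. Quadrant classification calls a pathway active
when its rescaled score strictly exceeds the threshold (default 0.5; a score
exactly at the threshold is inactive). The quadrant summary reports the
observed co-activation fraction and the independence expectation, which is
*exactly* the product of the marginal activation fractions.

For the co-activation deficit, three tests are offered. The default is the
one-sided Fisher exact test on the 2×2 activation table, the standard exact
test for mutual exclusivity. The transparent alternative — the binomial tail
of the co-activation count against the product-of-marginals rate — is kept as
`method = "binomial"`, but it is markedly conservative: the null rate is
estimated from the same table, and in our calibration runs (2,000 independent
tables, $n = 2000$, marginals 0.3) its type-I error at $\alpha = 0.05$ was
0.014 against 0.052 for Fisher. That measured miscalibration is why Fisher is
the default. A one-sided chi-square approximation rounds out the options.

Subtype association is a one-way fixed-effects ANOVA on rescaled scores,
with subtypes of fewer than 2 samples dropped; "high-activation" enrichment
counts the subtype composition of samples jointly exceeding the threshold in
all named pathways.

## Genomic correlates

Extreme activity subgroups (high-A/low-B versus low-A/high-B) use a symmetric
reading of the cutoff: the cutoff always names the stricter tail, so cutoff
0.5 means above/below the midpoint while cutoff 0.2 means beyond the outer
quintiles. A plain reading (both conditions at the cutoff itself) is
available via `rule = "plain"`.

Copy-number alteration calls use the conventional log2 tumor/normal
thresholds of ±0.5 in at least 20% of a subgroup's samples, evaluated within
each subgroup separately; genes altered in either direction in both
subgroups are removed as commonly altered, and a gene gained in one subgroup
but lost in the other counts as altered in both (the conservative reading).

The differential-methylation scan averages each probe over a centered window
of adjacent same-chromosome probes (default 5, truncated at chromosome ends)
and compares subgroups by a Welch two-sample t-test on the window means. A
literally *paired* test is impossible here — the subgroups are different
patients — so windowed aggregation plus an unpaired Welch test is the
implemented reading; with window size 1 the scan reduces exactly to a
per-probe Welch test, which is the tested limit case. Probes with $p < 0.1$
are retained. No per-feature FDR is applied; error control follows the
permutation route (label shuffles preserving group sizes, reporting the mean
retained fraction), with an optional Benjamini–Hochberg column (`fdr = TRUE`)
clearly outside the core procedure. Window overlap correlates neighbouring
probes, so the spread of the permutation fractions is wider than an
independent-test binomial would suggest — the reported spread is the
empirical one.

## The synthetic-data generator

The generator exists so every stage can be validated against known truth.

* **Training sets**: per-probe log2 baselines $N(7, 1)$, Gaussian noise of
  SD 1, and a $+\,\text{effect} \times \text{SD}$ shift (default 2) on the
  signature genes of activated samples; optional per-batch per-probe offsets.
* **Tumor compendia**: latent activities from a Gaussian copula whose Pearson
  parameter is $2 \sin(\pi \rho_s / 6)$ for the target Spearman matrix
  (including the strong negative EZH2–HDAC4 dependence, default $-0.7$),
  mapped to $[0,1]$ by the normal CDF; expression responds linearly in
  activity so that a fully active tumor matches an activated training sample.
  Subtype labels derive from the latent activities.
* **Genomic correlates**: copy-number background $N(0, 0.15^2)$ with planted
  ±0.8 subgroup-specific alterations; Beta(2,2) methylation with planted
  window shifts; two synthetic chromosomes.

Every generator is a pure function of its seed.

**What passing tests do and do not show.** The copula's normal-CDF map makes
latent activities *uniform* per pathway, so roughly half of all synthetic
tumors are truly active — unlike real compendia, where most tumors have a
pathway fully off and activities cluster at the extremes. Combined with a
perfectly separable training set (which leaves the probit decision boundary
identified only up to the wide between-class gap, so posterior-mean
probabilities ramp rather than saturate), the rescaled-score distribution is
top-heavy and the 0.5 threshold lands low in it: marginal activation
fractions on synthetic compendia come out around 0.8–0.98 rather than the
~0.3 seen in real tumor panels. Rank-based quantities (Spearman recovery of
the latent truth, typically ≥ 0.9) are unaffected, but absolute quadrant
fractions and the power of the deficit test at $n = 2000$ are: the deficit
is real but small in absolute terms, and its test rejects at $p < 0.01$ for
most but not all seeds. Tests on this generator therefore validate the
machinery and rank structure, not the absolute activation fractions of real
data.

## Numerical choices and degenerate inputs

* Quantile normalization ties receive the mean of the reference quantiles
  they span (tie averaging); normalization is idempotent to floating
  tolerance.
* The GAPDH 3'/5' degradation filter removes ratios strictly greater than 3;
  exactly 3.0 is kept. Samples without control intensities are kept with a
  warning rather than silently dropped.
* Probe-filter thresholds default to the 0.25 quantile for low signal,
  presence in ≥ 25% of samples, and the 0.25 variance quantile — placeholders
  in the absence of published values, all configurable.
* Batch adjustment is per-gene per-batch centering (optionally scaling) with
  global-mean restoration — a transparent location/scale stand-in for heavier
  batch-correction machinery, pluggable by design; under `"center"` each
  gene's global mean is preserved to 1e-9.
* Zero-variance signature genes in a projection target are dropped with a
  warning and the loadings re-normalized; an all-zero-variance target is an
  error.
* Degenerate rescaling (all probabilities equal) returns 0.5 everywhere,
  flagged.

## Problem sizes

The test suite and the acceptance script size their simulations to run in a
few minutes on one CPU: training sets of 1,000 probes with 10 samples per
class, compendia of 2,000 tumors, 1,000 methylation probes with 100 label
shuffles, 500-replicate calibration loops, and 20–50 seed repeats for
accuracy summaries. The probit oracle comparison uses a 401×401 coefficient
grid against 20,000 Gibbs draws.

## Known limitations

* The batch adjustment aligns means (and optionally scales); it is not a
  full distribution-matching or discrimination-based correction.
* The binomial deficit test is conservative (see above); the Fisher default
  conditions on estimated margins and is recommended.
* Cross-platform projection relies on shared identifiers only.
* The latent-to-expression map is linear; saturating or switch-like responses
  are out of scope.
* Survival analysis, gene-set enrichment, and raw-array preprocessing are
  deliberately outside the package: inputs are assumed already summarized to
  probe-level intensities.
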