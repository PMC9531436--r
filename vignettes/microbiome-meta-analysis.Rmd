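---
title: "Methods: meta-analysis of microbial community profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of microbial community profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Microbial community studies measure the same kind of object — a
sample-by-taxon abundance table — under wildly different protocols, and the
technical differences between sequencing runs, extraction kits, and studies
("batch effects") are often larger than the biology of interest. micrometa
provides a coherent set of tools for analyzing many such tables jointly:
batch correction tailored to zero-inflated count data, per-study
differential-abundance models pooled by meta-analysis, unsupervised
discovery of discrete (cluster) and continuous (gradient) population
structure that is reproducible *across* studies, and a simulation and
PERMANOVA harness with which every component is validated.

```{r, eval = FALSE}
library(micrometa)
```

# The batch-correction model

Non-zero counts of feature $p$ in sample $j$ of batch $i$ are modelled as

$$Y_{ijp} = \exp\{\beta_p' X_{ij} + \sigma_p(\gamma_{ip} + \delta_{ip}\,
\epsilon_{ijp})\} \times I_{ijp},$$

where $X_{ij}$ holds the intercept and biological covariates, $\sigma_p$ is
a feature-specific standardization factor, $(\gamma_{ip}, \delta_{ip})$ are
batch-specific location and scale parameters, $\epsilon_{ijp}$ is standard
normal, and $I_{ijp}$ is the zero indicator that carries the zero inflation
of microbial data. All estimation happens on the natural-log scale of the
non-zero counts only: a published version of the correction formula places
the raw count inside the exponent, but only the log-scale reading is
consistent with the model itself, and that is what this package implements.

Fitting proceeds feature by feature. A least-squares regression of
$\log Y$ on batch cell-means plus dummy-coded covariates yields
$\hat\beta_p$ and a pooled residual standard deviation $\hat\sigma_p$
(floored at $10^{-8}$ to survive degenerate features); the batch-free
standardized residuals then give frequentist per-batch means
$\hat\gamma_{ip}$ and standard deviations $\hat\delta_{ip}$. The grand
intercept is the batch-size-weighted mean of the batch cell-means, with the
weights recomputed per feature from its non-zero counts, because
zero-inflation makes every feature's effective design different.

These per-batch, per-feature estimates are then shrunken by parametric
empirical Bayes: across the features of one batch, locations get a normal
prior and squared scales an inverse-gamma prior, hyperparameters by method
of moments, posterior means by the standard iterative conditional update
(tolerance $10^{-4}$ on the maximum relative change, capped at 500
iterations). Shrinkage stabilizes the high-dimensional batch parameters at
realistic sample sizes; with fewer than three estimable features in a batch
it is skipped with a warning. The corrected value of a non-zero count is

$$\tilde Y_{ijp} = \exp\left\{\frac{\log Y_{ijp} - \hat\beta_p' X_{ij} -
\hat\gamma^*_{ip}\hat\sigma_p}{\hat\delta^*_{ip}} +
\hat\beta_p' X_{ij}\right\},$$

zeros are never touched, and each sample row is rescaled to its original
total. Three consequences deserve emphasis:

* **Presence/absence is invariant.** Zero counts stay zero; a batch-specific
  absence is never imputed. Substantial non-zero counts indicate biological
  presence, and the per-observation noise of an inflated zero cannot be
  inferred under this model, so correction is deliberately conservative.
* **Read depth is invariant.** Per-sample totals are conserved to $10^{-8}$
  relative; consequently a batch effect that is a *common* multiplicative
  factor on all features (equivalently, a depth difference) is
  compositionally invisible and is intentionally not "corrected".
* **Weak cells pass through.** A batch-feature pair with fewer than
  `min_nonzero = 2` non-zero observations (a standard deviation needs two
  points) is flagged and passed through unchanged ($\gamma^* = 0$,
  $\delta^* = 1$), as is any feature with fewer than two non-zero counts
  overall.

Covariates named in `correct_batch()` are *retained*: their fitted effects
are removed before standardization and added back, so confounded biology is
not absorbed into the batch parameters. A design in which a covariate is
collinear with batch is refused with the offending columns named, rather
than silently dropped.

# Differential abundance across studies

Within one study, `fit_study_model()` regresses arcsine-square-root
transformed relative abundances (the standard variance-stabilizing
transform for proportions; total-sum scaling is applied first) on the
exposure plus covariates, feature by feature. With repeated measures per
subject a random-intercept mixed model (REML) replaces ordinary least
squares; when its random-effect variance collapses to zero the fit
coincides with the plain linear model. Features absent in a study return
an explicit `"absent"` status — never a zero effect.

Study effects $\hat\beta_{ip} = \beta_p + \epsilon_{ip} + e_{ip}$ are pooled
by inverse-variance meta-analysis (`pool_effects()`): fixed effects, or
random effects with the between-study variance $\tau^2$ estimated by REML
(DerSimonian-Laird fallback on non-convergence). Two-sided p-values use the
normal approximation and are Benjamini-Hochberg adjusted across features.
Moderator models (`moderator_test()`) regress per-stratum effects on a
binary stratum label with random stratum effects; the moderator coefficient
is an interaction effect. For ordinal severity phenotypes,
`contrast_models()` produces the two pairwise contrasts against the lowest
level plus the incremental top-level effect from a joint model; the FDR
pool for the incremental effect is restricted to features already
significant in a pairwise contrast, because only for those is the
incremental question asked.

# Discrete structure: prediction strength

`prediction_strength()` quantifies whether $k$ clusters are *reproducible*:
samples are repeatedly split in half, both halves are PAM-clustered on
Bray-Curtis dissimilarities (Jaccard and root Jensen-Shannon are also
available), validation samples are classified to the nearest training
medoid, and $ps(k)$ is the minimum over validation clusters of the fraction
of same-cluster pairs co-classified by the training medoids. Defaults: 20
random splits at fraction 0.5 — the established convention for this
statistic — with $ps(1) = 1$ by definition and singleton validation
clusters contributing 1 (no pairs to violate). Ties in medoid assignment
break toward the lower medoid index. `generalized_prediction_strength()`
replaces random splits by study pairs: cluster study $i$ and study $i'$
separately, score study-$i'$ pairs under study-$i$ medoids, and average
over validation studies — the cross-study reproducibility of a clustering.
The selected cluster number is the $k \ge 2$ maximizing average prediction
strength; $k = 1$ is excluded from the argmax because its score is 1 by
convention. Calinski-Harabasz and average silhouette are reported alongside
via `cluster_strength_indices()`.

# Continuous structure: consensus loadings

Discrete clusters are rare in gut communities; gradients are common.
`discover_continuous()` runs per-study PCA on centered, transformed
abundances and keeps each study's top components up to 80% cumulative
variance (`threshold_v`); all cross-study component pairs are scored by
absolute cosine, edges above `threshold_s = 0.7` form a network, and
greedy modularity maximization (deterministic, seed-free — chosen over
stochastic alternatives so module membership is exactly reproducible)
yields modules of mutually similar loadings, singletons discarded. The
default 0.7 sits near the threshold that guarantees sign-consistency of
three-member modules; `sweep_threshold_s()` rebuilds the network over a 0.5–0.8 grid to check
how sensitive the modules are to this cutoff. Each module's members are sign-corrected (anchor
= first member in study/component lexicographic order) and averaged into a
consensus loading — the plain average, as a unit-norm variant changes only
the scale of scores, never their ranks; if sign correction cannot make all
pairwise cosines positive the module is dropped with a warning recommending
a higher `threshold_s`. Modules are ranked by the number of member
components, then by their total variance explained: a recurrent structure's
strength is how much variation it carries, not how tight its cosines are —
the tightest modules are often single-dominant-taxon axes. Per-sample
scores are centered projections onto a consensus loading, and
`validate_consensus()` checks a loading against an external study's top
three components at the same cosine cutoff.

# The simulator

`make_scenario()` generates every evaluation design from a zero-inflated
log-normal null, $Y_{ip} \sim \mathrm{LogN}(\mu_p, \sigma_p^2) \times
\mathrm{Bernoulli}(\pi_p)$, with metadata associations injected by the
moment-preserving re-standardization

$$\tilde Y_{ip} = \frac{1}{1+\phi}\left\{Y_{ip} + \phi\left[
\frac{(X_i - \mu^X)\,\sigma^Y_p}{\sigma^X} + \mu^Y_p\right]\right\},$$

which leaves the spiked feature's sample mean exactly and its variance
approximately unchanged while adding the association at strength $\phi$.
Negative post-spike values are truncated to zero (abundances must be
non-negative) and the truncated fraction is recorded. Zero entries
participate in the formula as written, so spiking can create presence; a
`nonzero_only` flag restricts spiking to originally present entries.
Categorical variables (batch, cluster) spike each targeted feature with one
level's indicator, levels assigned in rotation; each variable draws its own
target set of `pct_spiked` features. The exposure imbalance of the
confounded-null design is implemented as per-batch case fraction
$0.5 \pm \mathrm{imbalance}/2$.

The shipped default null (`default_null_params()`) is a fixed synthetic
parameter set drawn once from $\mu_p \sim N(4, 2^2)$, $\sigma_p \sim
U(0.5, 2)$, $\pi_p \sim \mathrm{Beta}(0.8, 1.2)$ truncated to
$[0.05, 1]$ — a heavy-tailed community with a few dominant taxa and a long
low-prevalence tail, the regime the correction's zero-handling exists for.
`fit_null_model()` refits these parameters on any real count table, which
is the recommended route when a training dataset is available.

**What the generator does not emulate.** Features are drawn independently,
so there is no ecological covariation beyond what spiking injects; and
prevalence $\pi_p$ is drawn independently of abundance $\mu_p$, whereas in
real stool communities dominant taxa are almost universally present. The
second gap matters for unsupervised evaluation: a dominant taxon with
intermediate prevalence creates a genuine, stable presence/absence
partition of samples, and cluster-number selection by prediction strength
can legitimately prefer that structure to a planted cluster label — a
behavior visible in this package's own discrete benchmark, and one batch
correction cannot (and should not) remove, since it is not a batch
artifact. Passing unsupervised benchmarks on this generator therefore says
less about real data than the supervised ones; refitting the null on a
real table is the antidote.

# The evaluation harness

`permanova_r2()` partitions a dissimilarity matrix by one variable at a
time (marginal testing) via the standard Gower-centered decomposition, with
permutation p-values computed as $(\text{count}+1)/(n_{\mathrm{perm}}+1)$
(2000 permutations by default, never exactly zero). Repeated measures use
blocked schemes: per-sample variables permute within subject blocks;
per-subject variables permute whole blocks (requiring equal block sizes, a
constraint of whole-block permutation). Conditioning on a covariate is
expressed by restricting the tested sample subset. `n_perm = 0` skips the
permutation test entirely when only the $R^2$ is needed.

The benchmark functions (`benchmark_correction()`, `benchmark_fpr()`,
`benchmark_discrete()`, `benchmark_continuous()`,
`benchmark_permanova_anchor()`) compose simulate → correct → analyze →
score and return per-replicate tibbles. Problem sizes used by the package's
own test suite were chosen as the smallest at which the qualitative
contrasts are stable: 20 replicates per design; 2–8 batches of 100–500
samples; 200–1000 features; 5–20% spiked; the discrete benchmark uses 10
random splits per prediction-strength estimate (half the component
default) and candidate $k \in 2..5$.

# Numerical choices and degenerate inputs

* Natural logs everywhere; $\sigma_p$ floored at $10^{-8}$; shrunken scales
  floored away from zero so pass-through cells never divide by zero.
* EB iteration: tolerance $10^{-4}$, cap 500; REML pooling: 100 iterations,
  then DerSimonian-Laird; saturated moderator designs fall back to the
  fixed-effects meta-regression (heterogeneity is inestimable there).
* Root Jensen-Shannon uses natural log with $0 \log 0 = 0$; Jaccard is
  presence/absence.
* Non-numeric covariate missingness becomes an explicit `"missing"` factor
  level; missing continuous covariates are refused, never imputed.
* Quality control (`filter_quality()`) removes samples with depth strictly
  below 3000 reads first, then keeps features exceeding $5\times10^{-5}$
  relative abundance (strict) in at least 10% (non-strict) of some study's
  samples; applying depth before prevalence is a documented ordering
  choice. With all thresholds at zero the filter is the identity.
* All stochastic components (simulator, splits, permutations) take explicit
  seeds and restore the caller's RNG state; results are pure functions of
  inputs and seed.

# Known limitations

Batch-specific absence is never corrected (by design); depth-like batch
effects are compositionally invisible after renormalization; the
independence and prevalence-abundance structure of the default simulator
null are idealized as described above; prediction strength's argmax is
known to favor coarse clusterings when cluster geometry is asymmetric; and
block-level permutation requires balanced blocks. The correction reduces —
rather than eliminates — batch differences at realistic sample sizes, since
empirical-Bayes shrinkage deliberately under-corrects what cannot be
confidently estimated.
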