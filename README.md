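# micrometa

Meta-analysis of microbial community profiles in R: batch-effect correction
for zero-inflated count data, differential-abundance testing pooled across
studies, and unsupervised discovery of population structure that reproduces
across studies — together with the zero-inflated log-normal simulator and
PERMANOVA harness used to validate every component.

Microbiome studies of the same phenotype rarely agree at face value:
sequencing run, extraction protocol, and study-level differences ("batch
effects") routinely explain more community variation than the biology.
micrometa is for analysts who hold several sample-by-taxon abundance tables
(or one table spanning several runs) and want to analyze them jointly
without letting technical structure masquerade as biology.

## The models at the core

**Batch correction.** Non-zero counts are modelled feature-wise as

    Y_ijp = exp{ beta_p' X_ij + sigma_p * (gamma_ip + delta_ip * eps_ijp) } * I_ijp

with batch-specific location/scale `(gamma_ip, delta_ip)`, retained
covariates `X`, and a zero indicator `I` carrying the zero inflation.
Batch parameters are shrunken by parametric empirical Bayes (normal prior
on locations, inverse-gamma on squared scales) and removed from the
log-scale non-zero counts; zeros are never touched and per-sample read
depth is conserved exactly.

**Meta-analysis of differential abundance.** Arcsine-square-root
transformed relative abundances are modelled per study (linear, or
random-intercept for repeated measures); per-study effects
`b_ip = beta_p + e_ip + u_ip` are pooled by fixed- or random-effects
(REML `tau^2`) inverse-variance meta-analysis, with moderator
(interaction) models and ordinal severity contrasts, and BH-FDR across
features.

**Population structure.** Discrete: PAM clustering on Bray-Curtis (or
Jaccard / root-JSD) evaluated by prediction strength `ps(k)` — the minimum
over validation clusters of the co-classification rate under training
medoids — and its cross-study generalization `gps(k)`. Continuous:
per-study PCA loadings linked across studies by absolute cosine similarity,
modularity modules of the resulting network, and sign-corrected consensus
loadings whose centered projections score each sample along a reproducible
gradient.

## Worked example

```r
library(micrometa)

# two sequencing batches, 50 samples each, 100 features; 10% of features
# carry a batch effect (strength 10), 10% a binary biological signal
sc <- make_scenario("batch_covariate", n_batches = 2, samples_per_batch = 50,
                    n_features = 100, pct_spiked = 0.1,
                    effect_batch = 10, effect_covariate = 10, seed = 42)
sc
#> # Simulation scenario 'batch_covariate': 100 samples x 100 features, 2 batches

corrected <- correct_batch(sc$table, sc$metadata,
                           covariates = c("pos_binary", "pos_continuous", "neg_binary"))
glance(attr(corrected, "fit"))
#> # A tibble: 1 × 6
#>   n_features n_batches n_covariate_columns n_uncorrectable n_pairs_uncorrected
#> 1        100         2                   3               0                  15

d_pre  <- bray_curtis(tss_normalize(sc$table))
d_post <- bray_curtis(tss_normalize(corrected))
rbind(pre  = sapply(c("batch", "pos_binary", "neg_binary"),
                    function(v) permanova_r2(d_pre,  sc$metadata, v, n_perm = 0)$r2),
      post = sapply(c("batch", "pos_binary", "neg_binary"),
                    function(v) permanova_r2(d_post, sc$metadata, v, n_perm = 0)$r2))
#>           batch pos_binary neg_binary
#> pre  0.06081938 0.04942589 0.01444218
#> post 0.05216822 0.05258276 0.01543164
```

The batch's share of community variance (PERMANOVA R²) drops after
correction, the spiked biological signal is retained (slightly sharpened),
and the negative control stays at its null level. Downstream, the corrected
table feeds the pooled differential-abundance model:

```r
res <- run_meta_da(corrected, sc$metadata, "pos_binary", study = "batch")
res
#> # Meta-analysis of 'pos_binary' (random effects): 100 features across
#> #   2 study units; 9 at q <= 0.05
dplyr::arrange(tidy(res), q)[1:3, c("feature_id", "beta", "q", "k")]
#>   feature_id   beta         q     k
#> 1 f0002      0.0155 8.60e-117     2
#> 2 f0055      0.0320 8.58e-112     2
#> 3 f0040      0.204  1.02e-111     2
```

`beta` is the pooled exposure effect on the arcsine-square-root scale of
relative abundance, `q` its BH-adjusted p-value, `k` the number of study
units contributing. `prediction_strength()` / `discover_continuous()`
take the same corrected table into unsupervised territory, and every
fitted object has `tidy()`, `glance()`, and `autoplot()` methods.

A thin command-line wrapper over the same functions lives at
`inst/cli/micrometa.R` (subcommands `simulate`, `correct`, `metada`,
`permanova`, `discrete`, `continuous`, `bench`), writing its resolved
configuration as JSON next to each run's outputs.

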