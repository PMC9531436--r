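#' Simulation benchmarks of every component
#'
#' These functions run the package's synthetic-data evaluation designs end
#' to end — simulate, optionally batch-correct, analyze, score — and return
#' per-replicate tidy results. They are the programmatic equivalent of a
#' `bench` command and the basis of the package's acceptance checks.
#'
#' @name benchmarks
NULL

# Bray-Curtis of the TSS-normalized table
bench_dist <- function(tab) {
  bray_curtis(tss_normalize(tab))
}

#' @describeIn benchmarks Batch-correction benchmark: simulates the
#'   batch + positive/negative-control design, corrects with the control
#'   variables as covariates, and reports marginal PERMANOVA `R2` for every
#'   variable before and after correction.
#' @param n_reps Number of simulation replicates.
#' @param n_batches,samples_per_batch,n_features,pct_spiked,effect_batch,effect_covariate,n_clusters,imbalance
#'   Scenario parameters, see [make_scenario()].
#' @param seed Base integer seed; replicate `r` uses `seed + r`.
#' @return A tibble of per-replicate results (layout per function).
#' @export
benchmark_correction <- function(n_reps = 20, n_batches = 4,
                                 samples_per_batch = 100, n_features = 1000,
                                 pct_spiked = 0.05, effect_batch = 10,
                                 effect_covariate = 10, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sc <- make_scenario("batch_covariate",
      n_batches = n_batches, samples_per_batch = samples_per_batch,
      n_features = n_features, pct_spiked = pct_spiked,
      effect_batch = effect_batch, effect_covariate = effect_covariate,
      seed = seed + r
    )
    corrected <- correct_batch(sc$table, sc$metadata,
      batch = "batch",
      covariates = c("pos_binary", "pos_continuous", "neg_binary")
    )
    vars <- c("batch", "pos_binary", "pos_continuous", "neg_binary")
    pre <- bench_dist(sc$table)
    post <- bench_dist(corrected)
    purrr::map_dfr(vars, function(v) {
      tibble::tibble(
        rep = r, variable = v,
        r2_pre = permanova_r2(pre, sc$metadata, v, n_perm = 0)$r2,
        r2_post = permanova_r2(post, sc$metadata, v, n_perm = 0)$r2
      )
    })
  })
}

#' @describeIn benchmarks False-positive-rate benchmark on the confounded
#'   null design: per replicate, the FPR (fraction of features with nominal
#'   p < 0.05 for the exposure) of a naive pooled linear model that ignores
#'   the study structure, and of batch correction followed by per-study
#'   models pooled by random-effects meta-analysis.
#' @export
benchmark_fpr <- function(n_reps = 20, n_batches = 2, samples_per_batch = 100,
                          n_features = 200, pct_spiked = 0.1,
                          effect_batch = 10, imbalance = 0.8, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sc <- make_scenario("confounded_null",
      n_batches = n_batches, samples_per_batch = samples_per_batch,
      n_features = n_features, pct_spiked = pct_spiked,
      effect_batch = effect_batch, imbalance = imbalance, seed = seed + r
    )
    # naive arm: one pooled model, study structure ignored
    naive <- fit_study_model(sc$table, sc$metadata, "exposure")
    z <- naive$effect / naive$se
    p_naive <- 2 * stats::pt(-abs(z), df = naive$n_used - 2L)
    # meta-analysis arm: correct, then per-study models pooled
    corrected <- correct_batch(sc$table, sc$metadata, batch = "batch")
    md <- run_meta_da(corrected, sc$metadata, "exposure", study = "batch")
    tibble::tibble(
      rep = r,
      fpr_naive = false_positive_rate(p_naive),
      fpr_meta = false_positive_rate(md$pooled$p)
    )
  })
}

#' @describeIn benchmarks Discrete-structure benchmark: simulates known
#'   clusters confounded with batch, selects the cluster number by maximum
#'   average prediction strength before and after correction, and scores
#'   success against the simulated truth.
#' @param k_range Candidate cluster numbers for selection.
#' @param n_iter Random splits per prediction-strength estimate.
#' @export
benchmark_discrete <- function(n_reps = 20, n_batches = 2,
                               samples_per_batch = 250, n_features = 1000,
                               pct_spiked = 0.2, effect_batch = 10,
                               effect_covariate = 10, n_clusters = 3,
                               k_range = 2:5, n_iter = 10, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sc <- make_scenario("discrete_clusters",
      n_batches = n_batches, samples_per_batch = samples_per_batch,
      n_features = n_features, pct_spiked = pct_spiked,
      effect_batch = effect_batch, effect_covariate = effect_covariate,
      n_clusters = n_clusters, seed = seed + r
    )
    corrected <- correct_batch(sc$table, sc$metadata, batch = "batch")
    purrr::map_dfr(
      list(pre = sc$table, post = corrected),
      function(tab) {
        ev <- prediction_strength(bench_dist(tab),
          k_range = k_range,
          n_iter = n_iter, seed = seed + r
        )
        k_hat <- select_k(ev)
        tibble::tibble(
          rep = r, k_selected = k_hat,
          success = k_hat == sc$truth$n_clusters
        )
      },
      .id = "arm"
    )
  })
}

#' @describeIn benchmarks Continuous-structure benchmark: simulates a known
#'   gradient confounded with batch, runs the consensus-gradient discovery
#'   on per-batch tables before and after correction, scores the strongest
#'   module's per-sample score against the simulated gradient
#'   (sign-invariant absolute correlations).
#' @param threshold_v,threshold_s See [discover_continuous()].
#' @export
benchmark_continuous <- function(n_reps = 20, n_batches = 4,
                                 samples_per_batch = 100, n_features = 1000,
                                 pct_spiked = 0.2, effect_batch = 10,
                                 effect_covariate = 10, threshold_v = 0.8,
                                 threshold_s = 0.7, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sc <- make_scenario("continuous_gradient",
      n_batches = n_batches, samples_per_batch = samples_per_batch,
      n_features = n_features, pct_spiked = pct_spiked,
      effect_batch = effect_batch, effect_covariate = effect_covariate,
      seed = seed + r
    )
    corrected <- correct_batch(sc$table, sc$metadata, batch = "batch")
    purrr::map_dfr(
      list(pre = sc$table, post = corrected),
      function(tab) {
        m <- ft_values(tab)
        split_tabs <- lapply(split(seq_len(nrow(m)), sc$metadata$batch), function(i) {
          feature_table(m[i, , drop = FALSE])
        })
        res <- discover_continuous(split_tabs,
          threshold_v = threshold_v,
          threshold_s = threshold_s
        )
        if (!length(res$consensus)) {
          return(tibble::tibble(
            rep = r, n_modules = 0L,
            pearson = NA_real_, spearman = NA_real_
          ))
        }
        sc_scores <- assign_scores(tab, res$consensus[[1L]])
        met <- recovery_metrics(sc$truth$gradient, sc_scores$score)
        tibble::tibble(
          rep = r, n_modules = length(res$consensus),
          pearson = met$pearson, spearman = met$spearman
        )
      },
      .id = "arm"
    )
  })
}

#' @describeIn benchmarks PERMANOVA anchor: the large meta-analysis-scale
#'   design (defaults: 8 batches of 500 samples, 200 features, 10% of
#'   features spiked with batch and 10% with a binary exposure, both at
#'   strength 10) whose marginal Bray-Curtis PERMANOVA `R2` for batch and
#'   exposure anchor the simulation to real multi-study collections.
#'   Returns per-replicate `r2_batch` and `r2_exposure` (fractions).
#' @export
benchmark_permanova_anchor <- function(n_reps = 5, n_batches = 8,
                                       samples_per_batch = 500,
                                       n_features = 200, pct_spiked = 0.1,
                                       effect_batch = 10,
                                       effect_covariate = 10, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sc <- make_scenario("batch_covariate",
      n_batches = n_batches, samples_per_batch = samples_per_batch,
      n_features = n_features, pct_spiked = pct_spiked,
      effect_batch = effect_batch, effect_covariate = effect_covariate,
      effect_continuous = 0, seed = seed + r
    )
    d <- bench_dist(sc$table)
    tibble::tibble(
      rep = r,
      r2_batch = permanova_r2(d, sc$metadata, "batch", n_perm = 0)$r2,
      r2_exposure = permanova_r2(d, sc$metadata, "pos_binary", n_perm = 0)$r2
    )
  })
}
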