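#' Partition-around-medoids clustering of a dissimilarity matrix
#'
#' Thin wrapper over [cluster::pam()] (BUILD + SWAP on a precomputed
#' dissimilarity), the clustering used throughout the discrete structure
#' discovery component. Deterministic given the dissimilarity.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of clusters, `2 <= k < n`.
#' @return A list of class `pam_clustering`: `k`, `medoids` (sample
#'   indices), `labels` (integer vector in `1..k`, named by sample id).
#' @export
pam_cluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n || k < 1L) stop("need 1 <= k < n samples", call. = FALSE)
  if (k == 1L) {
    return(structure(
      list(k = 1L, medoids = which.min(colSums(d)), labels = stats::setNames(rep(1L, n), rownames(d))),
      class = "pam_clustering"
    ))
  }
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE, cluster.only = FALSE)
  structure(
    list(
      k = k, medoids = fit$id.med,
      labels = stats::setNames(as.integer(fit$clustering), rownames(d))
    ),
    class = "pam_clustering"
  )
}

#' Classify samples to the nearest training medoid
#'
#' @param d_to_medoids Matrix of dissimilarities, one row per sample to
#'   classify and one column per training medoid (column order = cluster
#'   order). Ties go to the lowest medoid index.
#' @return Integer cluster labels.
#' @export
classify_to_medoids <- function(d_to_medoids) {
  d_to_medoids <- as.matrix(d_to_medoids)
  apply(d_to_medoids, 1L, which.min)
}

#' Prediction strength over a range of cluster numbers
#'
#' For each candidate `k`, samples are repeatedly split at random into
#' training and validation halves; both halves are PAM-clustered, validation
#' samples are additionally classified to the nearest training medoid, and
#' the prediction strength `ps(k)` is the minimum, over validation clusters,
#' of the fraction of same-cluster validation pairs that the training
#' medoids also co-classify. Averaged over splits. `ps(1) = 1` by
#' definition, and singleton validation clusters contribute 1 (no pairs to
#' violate).
#'
#' @param t A [feature_table()] (or a precomputed dissimilarity matrix).
#' @param k_range Candidate cluster numbers (default `2:6`; `1` may be
#'   included and always scores 1).
#' @param n_iter Number of random splits (default `20`).
#' @param train_frac Training fraction of each split (default `0.5`).
#' @param dissimilarity Passed to [dissimilarity()] when `t` is a table.
#' @param seed Optional integer seed for the splits.
#' @return An object of class `cluster_evaluation`: tibble with columns
#'   `k`, `ps` (mean over splits), `ps_sd`.
#' @export
prediction_strength <- function(t, k_range = 2:6, n_iter = 20,
                                train_frac = 0.5,
                                dissimilarity = "bray", seed = NULL) {
  d <- if (is.matrix(t) && nrow(t) == ncol(t) && all(abs(diag(t)) < 1e-12)) {
    t
  } else {
    dissimilarity(if (is.matrix(t)) t else t, method = dissimilarity)
  }
  n <- nrow(d)
  if (n < 2L * max(k_range)) stop("need n >= 2 * max(k_range)", call. = FALSE)
  if (!is.null(seed)) {
    state <- local_seed(seed)
    on.exit(restore_seed(state), add = TRUE)
  }
  ps_mat <- matrix(NA_real_, n_iter, length(k_range))
  for (it in seq_len(n_iter)) {
    tr <- sort(sample.int(n, round(train_frac * n)))
    va <- setdiff(seq_len(n), tr)
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      if (k == 1L) {
        ps_mat[it, ki] <- 1
        next
      }
      fit_tr <- pam_cluster(d[tr, tr, drop = FALSE], k)
      fit_va <- pam_cluster(d[va, va, drop = FALSE], k)
      cls <- classify_to_medoids(d[va, tr[fit_tr$medoids], drop = FALSE])
      ps_mat[it, ki] <- ps_score(fit_va$labels, cls, k)
    }
  }
  structure(
    tibble::tibble(
      k = k_range,
      ps = colMeans(ps_mat),
      ps_sd = apply(ps_mat, 2L, stats::sd)
    ),
    class = c("cluster_evaluation", class(tibble::tibble()))
  )
}

# min over validation clusters of the co-classified pair fraction
ps_score <- function(val_labels, train_classification, k) {
  frac <- vapply(seq_len(k), function(l) {
    members <- which(val_labels == l)
    nl <- length(members)
    if (nl < 2L) {
      return(1) # singleton: no pairs to violate
    }
    cnt <- table(train_classification[members])
    sum(cnt * (cnt - 1)) / (nl * (nl - 1))
  }, numeric(1))
  min(frac)
}

#' Generalized prediction strength across studies
#'
#' Cross-study analogue of [prediction_strength()]: each study is clustered
#' independently, and for an ordered (training, validation) study pair the
#' validation study's intra-cluster pairs are scored for co-classification
#' under the training study's medoids. Averages over validation studies
#' (excluding the training study itself) summarize each training study.
#'
#' @param tables Named list of [feature_table()]s sharing one feature space.
#' @param k Number of clusters.
#' @param dissimilarity Dissimilarity method, see [dissimilarity()].
#' @return A list: `gps` (matrix, training studies in rows, validation in
#'   columns, `NA` diagonal) and `mean` (per-training-study average).
#' @export
generalized_prediction_strength <- function(tables, k, dissimilarity = "bray") {
  stopifnot(length(tables) >= 2L)
  feats <- lapply(tables, function(x) colnames(ft_values(x)))
  if (!all(vapply(feats[-1L], identical, logical(1), feats[[1L]]))) {
    stop("tables must share an identical feature space", call. = FALSE)
  }
  S <- length(tables)
  nm <- names(tables) %||% paste0("study", seq_len(S))
  mats <- lapply(tables, ft_values)
  fits <- lapply(mats, function(m) {
    pam_cluster(dissimilarity(m, method = dissimilarity), k)
  })
  gps <- matrix(NA_real_, S, S, dimnames = list(train = nm, validation = nm))
  for (i in seq_len(S)) {
    med <- mats[[i]][fits[[i]]$medoids, , drop = FALSE]
    for (ip in seq_len(S)) {
      if (ip == i) next
      comb <- rbind(mats[[ip]], med)
      dfull <- dissimilarity(comb, method = dissimilarity)
      nval <- nrow(mats[[ip]])
      cls <- classify_to_medoids(dfull[seq_len(nval), nval + seq_len(k), drop = FALSE])
      gps[i, ip] <- ps_score(fits[[ip]]$labels, cls, k)
    }
  }
  list(gps = gps, mean = rowMeans(gps, na.rm = TRUE))
}

#' Internal cluster-strength indices
#'
#' Calinski-Harabasz index (between/within variance ratio, computed from
#' centroids in the feature space) and average silhouette width (from the
#' dissimilarity matrix, via [cluster::silhouette()]).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param labels Integer cluster labels (at least two clusters).
#' @param data Optional samples-by-features matrix for the
#'   Calinski-Harabasz index; when omitted, `ch` is `NA`.
#' @return One-row tibble with `calinski_harabasz` and `avg_silhouette`.
#' @export
cluster_strength_indices <- function(d, labels, data = NULL) {
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2L) stop("indices undefined for a single cluster", call. = FALSE)
  sil <- cluster::silhouette(labels, dmatrix = as.matrix(d))
  ch <- NA_real_
  if (!is.null(data)) {
    data <- as.matrix(data)
    n <- nrow(data)
    grand <- colMeans(data)
    ssb <- 0
    ssw <- 0
    for (l in unique(labels)) {
      sub <- data[labels == l, , drop = FALSE]
      cen <- colMeans(sub)
      ssb <- ssb + nrow(sub) * sum((cen - grand)^2)
      ssw <- ssw + sum(sweep(sub, 2L, cen)^2)
    }
    ch <- (ssb / (k - 1)) / (ssw / (n - k))
  }
  tibble::tibble(
    calinski_harabasz = ch,
    avg_silhouette = mean(sil[, "sil_width"])
  )
}

#' Evaluate cluster numbers across dissimilarities and indices
#'
#' Full grid of dissimilarity metric by cluster number: average prediction
#' strength (within each table) plus Calinski-Harabasz and average
#' silhouette of the PAM solution on the full table; with several tables,
#' the cross-study mean generalized prediction strength is added.
#'
#' @param tables A [feature_table()] or named list of them (shared feature
#'   space).
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @param dissimilarities Subset of `c("bray", "jaccard", "rjsd")`.
#' @param n_iter Splits per prediction-strength estimate.
#' @param seed Optional integer seed.
#' @return A tibble: `table`, `dissimilarity`, `k`, `ps`, `gps` (NA for a
#'   single table), `calinski_harabasz`, `avg_silhouette`.
#' @export
evaluate_k_range <- function(tables, k_range = 2:6,
                             dissimilarities = c("bray", "jaccard", "rjsd"),
                             n_iter = 20, seed = NULL) {
  single <- inherits(tables, "feature_tbl") || !is.list(tables)
  if (single) tables <- list(table1 = tables)
  nm <- names(tables) %||% paste0("table", seq_along(tables))
  if (!is.null(seed)) {
    state <- local_seed(seed)
    on.exit(restore_seed(state), add = TRUE)
  }
  out <- list()
  for (dm in dissimilarities) {
    gps_k <- if (length(tables) >= 2L) {
      lapply(k_range, function(k) {
        generalized_prediction_strength(tables, k, dissimilarity = dm)$mean
      })
    } else {
      NULL
    }
    for (s in seq_along(tables)) {
      m <- ft_values(tables[[s]])
      d <- dissimilarity(m, method = dm)
      ev <- prediction_strength(d, k_range = k_range, n_iter = n_iter)
      idx <- purrr::map_dfr(k_range, function(k) {
        lab <- pam_cluster(d, k)$labels
        cluster_strength_indices(d, lab, data = arcsin_sqrt(m / rowSums(m)))
      })
      out[[length(out) + 1L]] <- tibble::tibble(
        table = nm[s], dissimilarity = dm, k = k_range, ps = ev$ps,
        gps = if (is.null(gps_k)) NA_real_ else vapply(gps_k, `[[`, numeric(1), s),
        calinski_harabasz = idx$calinski_harabasz,
        avg_silhouette = idx$avg_silhouette
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Select the number of clusters by maximum prediction strength
#'
#' @param evaluation A `cluster_evaluation` (or tibble with `k` and `ps`).
#' @return The `k` (>= 2) maximizing average prediction strength; ties go
#'   to the smallest k.
#' @export
select_k <- function(evaluation) {
  ev <- evaluation[evaluation$k >= 2L, ]
  ev$k[which.max(ev$ps)]
}

#' Plot prediction strength against cluster number
#'
#' @param object A `cluster_evaluation` from [prediction_strength()].
#' @param threshold Reference line for a "strong" prediction strength
#'   (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_evaluation <- function(object, threshold = 0.9, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$ps)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(.data$ps - .data$ps_sd, 0),
        ymax = pmin(.data$ps + .data$ps_sd, 1)
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "number of clusters k", y = "average prediction strength") +
    ggplot2::theme_minimal()
}
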