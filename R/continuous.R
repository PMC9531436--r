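#' Top principal-component loadings of a study
#'
#' PCA of the per-feature-centered, arcsine-square-root transformed relative
#' abundances of one study. The smallest number of leading components whose
#' cumulative variance explained reaches `threshold_v` is retained.
#'
#' @param t A [feature_table()] with at least 3 samples (counts or
#'   relative; transformed internally), or an already-transformed numeric
#'   matrix.
#' @param threshold_v Cumulative variance-explained threshold in `(0, 1]`
#'   (default `0.80`).
#' @return A list of class `pc_loadings`: `loadings` (features-by-J matrix,
#'   unit-norm columns), `var_explained` (fractions, all components),
#'   `n_kept`.
#' @export
pca_top_loadings <- function(t, threshold_v = 0.80) {
  x <- if (is.matrix(t)) t else transformed_abundance(t)
  if (nrow(x) < 3L) stop("PCA needs >= 3 samples", call. = FALSE)
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("constant table: no variance to decompose", call. = FALSE)
  sv <- svd(x)
  ve <- sv$d^2 / sum(sv$d^2)
  keep <- ve > 1e-12
  ve <- ve[keep]
  rot <- sv$v[, keep, drop = FALSE]
  rownames(rot) <- colnames(x)
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  J <- which(cumsum(ve) >= threshold_v - 1e-12)[1L]
  if (is.na(J)) J <- length(ve)
  structure(
    list(
      loadings = rot[, seq_len(J), drop = FALSE],
      var_explained = ve, n_kept = J
    ),
    class = "pc_loadings"
  )
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length and positive norm.
#' @return `sum(u * v) / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Build the cross-study network of similar PC loadings
#'
#' Nodes are the retained principal components of each study; an undirected
#' edge joins two components of *different* studies when the absolute
#' cosine of their loading vectors exceeds `threshold_s`. Feature spaces are
#' aligned by identifier intersection, with loadings restricted and
#' re-normalized to unit length.
#'
#' @param loading_sets Named list of [pca_top_loadings()] results (>= 2
#'   studies).
#' @param threshold_s Edge threshold on `|cos|` in `(0, 1)` (default `0.7`).
#' @return A list of class `pc_network`: `nodes` (tibble `node`, `study`,
#'   `pc`, `var_explained`), `edges` (tibble `from`, `to`, `weight`),
#'   `loadings` (aligned feature-by-node matrix), `threshold_s`,
#'   `dropped_features` (fraction lost in alignment per study).
#' @export
build_pc_network <- function(loading_sets, threshold_s = 0.7) {
  stopifnot(length(loading_sets) >= 2L, threshold_s > 0, threshold_s < 1)
  nm <- names(loading_sets)
  if (is.null(nm)) nm <- paste0("study", seq_along(loading_sets))
  feats <- Reduce(intersect, lapply(loading_sets, function(l) rownames(l$loadings)))
  if (length(feats) < 2L) stop("no shared feature space across studies", call. = FALSE)
  dropped <- vapply(loading_sets, function(l) {
    1 - length(feats) / nrow(l$loadings)
  }, numeric(1))

  cols <- list()
  nodes <- list()
  for (s in seq_along(loading_sets)) {
    L <- loading_sets[[s]]$loadings[feats, , drop = FALSE]
    L <- sweep(L, 2L, sqrt(colSums(L^2)), "/") # re-normalize after restriction
    colnames(L) <- paste(nm[s], colnames(loading_sets[[s]]$loadings), sep = ".")
    cols[[s]] <- L
    nodes[[s]] <- tibble::tibble(
      node = colnames(L), study = nm[s],
      pc = seq_len(ncol(L)),
      var_explained = loading_sets[[s]]$var_explained[seq_len(ncol(L))]
    )
  }
  W <- do.call(cbind, cols)
  nodes <- dplyr::bind_rows(nodes)
  cs <- crossprod(W) # unit columns: cosine matrix
  same_study <- outer(nodes$study, nodes$study, "==")
  keep <- abs(cs) > threshold_s & !same_study & upper.tri(cs)
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = nodes$node[idx[, 1L]],
    to = nodes$node[idx[, 2L]],
    weight = abs(cs[idx]),
    cosine = cs[idx]
  )
  structure(
    list(
      nodes = nodes, edges = edges, loadings = W,
      threshold_s = threshold_s, dropped_features = dropped
    ),
    class = "pc_network"
  )
}

#' Detect densely connected modules of PCs by modularity
#'
#' Greedy (deterministic, agglomerative) modularity maximization on the
#' weighted PC network; singleton communities are discarded, since a module
#' must span at least two studies to evidence a recurrent signal.
#'
#' @param net A [build_pc_network()] result.
#' @return A list of character vectors of node ids, ordered by decreasing
#'   module size, then decreasing total variance explained by the member
#'   components (the natural ranking of how strong a recurrent structure
#'   is), then decreasing mean internal edge weight.
#' @export
detect_modules <- function(net) {
  if (!nrow(net$edges)) {
    return(list())
  }
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = net$nodes$node
  )
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(comm)
  mods <- split(names(mem), mem)
  mods <- Filter(function(m) length(m) >= 2L, mods)
  if (!length(mods)) {
    return(list())
  }
  mean_w <- vapply(mods, function(m) {
    e <- net$edges[net$edges$from %in% m & net$edges$to %in% m, ]
    if (nrow(e)) mean(e$weight) else 0
  }, numeric(1))
  ve_col <- net$nodes[["var_explained"]] %||% rep(0, nrow(net$nodes))
  tot_ve <- vapply(mods, function(m) {
    sum(ve_col[match(m, net$nodes$node)], na.rm = TRUE)
  }, numeric(1))
  ord <- order(-lengths(mods), -tot_ve, -mean_w)
  unname(mods[ord])
}

#' Consensus loading of a PC module
#'
#' Sign-corrects the module's loading vectors (anchor = first member in
#' study/PC lexicographic order; every other member is flipped to a
#' positive cosine with it), verifies that all pairwise cosines are then
#' positive, and averages. A failure of the verification means the module
#' is sign-inconsistent and a higher `threshold_s` is recommended.
#'
#' @param net A [build_pc_network()] result.
#' @param members Character vector of node ids (>= 2) forming the module.
#' @param unit_norm If `TRUE`, the consensus is re-normalized to unit
#'   length; default `FALSE` keeps the plain average.
#' @return A list of class `consensus_loading`: `w` (named numeric
#'   consensus vector), `members`, `signs` (the flips applied), `mean_cos`.
#' @export
consensus_loading <- function(net, members, unit_norm = FALSE) {
  stopifnot(length(members) >= 2L, all(members %in% colnames(net$loadings)))
  members <- sort(members)
  L <- net$loadings[, members, drop = FALSE]
  cs <- crossprod(L)
  signs <- sign(cs[, 1L])
  signs[signs == 0] <- 1
  L <- sweep(L, 2L, signs, "*")
  cs2 <- crossprod(L)
  if (any(cs2 < 0)) {
    stop(
      "sign-inconsistent module: some loading pairs keep negative cosines ",
      "after sign correction; a higher threshold_s is recommended",
      call. = FALSE
    )
  }
  w <- rowMeans(L)
  if (unit_norm) w <- w / sqrt(sum(w^2))
  structure(
    list(
      w = w, members = members, signs = signs,
      mean_cos = mean(cs2[upper.tri(cs2)])
    ),
    class = "consensus_loading"
  )
}

#' Discover continuous population structure across studies
#'
#' Orchestrates the continuous-structure pipeline: per-study PCA
#' ([pca_top_loadings()]), the cross-study loading network
#' ([build_pc_network()]), modularity modules ([detect_modules()]), and one
#' consensus loading per module ([consensus_loading()]). Modules come
#' ordered by size, so the first consensus is the strongest recurrent
#' gradient.
#'
#' @param tables Named list of [feature_table()]s (the training studies).
#' @param threshold_v,threshold_s See [pca_top_loadings()] and
#'   [build_pc_network()].
#' @param unit_norm Passed to [consensus_loading()].
#' @return A list of class `continuous_structure`: `loading_sets`, `network`,
#'   `modules`, `consensus` (list of `consensus_loading`).
#' @export
discover_continuous <- function(tables, threshold_v = 0.80, threshold_s = 0.7,
                                unit_norm = FALSE) {
  stopifnot(length(tables) >= 2L)
  if (is.null(names(tables))) names(tables) <- paste0("study", seq_along(tables))
  loading_sets <- lapply(tables, pca_top_loadings, threshold_v = threshold_v)
  net <- build_pc_network(loading_sets, threshold_s = threshold_s)
  modules <- detect_modules(net)
  consensus <- lapply(modules, function(m) {
    tryCatch(consensus_loading(net, m, unit_norm = unit_norm),
      error = function(e) {
        warning(
          "dropping sign-inconsistent module {",
          paste(m, collapse = ", "),
          "}; a higher threshold_s is recommended",
          call. = FALSE
        )
        NULL
      }
    )
  })
  keep <- !vapply(consensus, is.null, logical(1))
  modules <- modules[keep]
  consensus <- consensus[keep]
  structure(
    list(
      loading_sets = loading_sets, network = net,
      modules = modules, consensus = consensus
    ),
    class = "continuous_structure"
  )
}

#' Assign per-sample continuous scores from a consensus loading
#'
#' Projects per-feature-centered, transformed abundances onto a consensus
#' loading: `score = centered transformed row . W`. Only features present
#' in both the table and the loading contribute.
#'
#' @param t A [feature_table()] (transformed internally) or transformed
#'   matrix.
#' @param w A [consensus_loading()] or named numeric vector of feature
#'   weights.
#' @return A tibble `sample_id`, `score`.
#' @export
assign_scores <- function(t, w) {
  if (inherits(w, "consensus_loading")) w <- w$w
  x <- if (is.matrix(t)) t else transformed_abundance(t)
  feats <- intersect(colnames(x), names(w))
  if (!length(feats)) stop("no shared features between table and loading", call. = FALSE)
  xc <- scale(x[, feats, drop = FALSE], center = TRUE, scale = FALSE)
  tibble::tibble(
    sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    score = drop(xc %*% w[feats])
  )
}

#' Validate a consensus loading in an external study
#'
#' The consensus is validated when its maximum absolute cosine with the
#' validation study's top principal-component loadings exceeds
#' `threshold_s`. The number of top PCs considered is fixed (default 3)
#' rather than variance-based.
#'
#' @param w A [consensus_loading()] or named numeric vector.
#' @param t_val Validation [feature_table()].
#' @param n_top_pcs Number of top validation PCs compared (default `3`).
#' @param threshold_s Validation cutoff on `|cos|` (default `0.7`).
#' @return One-row tibble: `max_abs_cosine`, `best_pc`, `validated`.
#' @export
validate_consensus <- function(w, t_val, n_top_pcs = 3, threshold_s = 0.7) {
  if (inherits(w, "consensus_loading")) w <- w$w
  pl <- pca_top_loadings(t_val, threshold_v = 1)
  J <- min(n_top_pcs, ncol(pl$loadings))
  L <- pl$loadings[, seq_len(J), drop = FALSE]
  feats <- intersect(rownames(L), names(w))
  if (length(feats) < 2L) stop("no shared features with validation study", call. = FALSE)
  cosines <- vapply(seq_len(J), function(j) {
    abs(cosine_similarity(w[feats], L[feats, j]))
  }, numeric(1))
  tibble::tibble(
    max_abs_cosine = max(cosines),
    best_pc = which.max(cosines),
    validated = max(cosines) > threshold_s
  )
}

#' Sensitivity sweep over the PC-similarity threshold
#'
#' Rebuilds the loading network and its modules across a grid of
#' `threshold_s` values, summarizing how edge and module counts react —
#' robust modules reappear across neighbouring thresholds.
#'
#' @param loading_sets Named list of [pca_top_loadings()] results.
#' @param thresholds Grid of similarity cutoffs (default `seq(0.5, 0.8,
#'   by = 0.05)`).
#' @return A tibble: `threshold_s`, `n_edges`, `n_modules`,
#'   `largest_module`, `n_sign_inconsistent`.
#' @export
sweep_threshold_s <- function(loading_sets, thresholds = seq(0.5, 0.8, by = 0.05)) {
  purrr::map_dfr(thresholds, function(th) {
    net <- build_pc_network(loading_sets, threshold_s = th)
    mods <- detect_modules(net)
    bad <- sum(vapply(mods, function(m) {
      inherits(try(consensus_loading(net, m), silent = TRUE), "try-error")
    }, logical(1)))
    tibble::tibble(
      threshold_s = th, n_edges = nrow(net$edges),
      n_modules = length(mods),
      largest_module = if (length(mods)) max(lengths(mods)) else 0L,
      n_sign_inconsistent = bad
    )
  })
}

#' @export
print.continuous_structure <- function(x, ...) {
  cat(
    "# Continuous structure: ", length(x$loading_sets), " studies, ",
    nrow(x$network$nodes), " PC nodes, ", nrow(x$network$edges), " edges, ",
    length(x$modules), " module(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a continuous-structure result
#'
#' @param x A `continuous_structure` from [discover_continuous()].
#' @param ... Unused.
#' @return A long tibble of consensus loadings: `module`, `feature_id`,
#'   `weight`.
#' @export
tidy.continuous_structure <- function(x, ...) {
  purrr::imap_dfr(x$consensus, function(cl, k) {
    tibble::tibble(
      module = k, feature_id = names(cl$w), weight = unname(cl$w)
    )
  })
}

#' @rdname tidy.continuous_structure
#' @export
glance.continuous_structure <- function(x, ...) {
  tibble::tibble(
    n_studies = length(x$loading_sets),
    n_nodes = nrow(x$network$nodes),
    n_edges = nrow(x$network$edges),
    n_modules = length(x$modules),
    threshold_s = x$network$threshold_s
  )
}

#' Plot the PC-loading network
#'
#' Nodes (study PCs) on a study-by-PC grid with edges weighted by absolute
#' cosine similarity; module members are coloured.
#'
#' @param object A `continuous_structure`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.continuous_structure <- function(object, ...) {
  nd <- object$network$nodes
  nd$x <- as.integer(factor(nd$study))
  nd$y <- nd$pc
  nd$module <- NA_character_
  for (k in seq_along(object$modules)) {
    nd$module[nd$node %in% object$modules[[k]]] <- paste0("module ", k)
  }
  ed <- object$network$edges
  ed <- dplyr::left_join(ed, nd[, c("node", "x", "y")], by = c(from = "node"))
  ed <- dplyr::left_join(ed, nd[, c("node", "x", "y")],
    by = c(to = "node"), suffix = c("", "_to")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
        linewidth = .data$weight
      ),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$module),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::scale_x_continuous(
      breaks = seq_along(levels(factor(nd$study))),
      labels = levels(factor(nd$study))
    ) +
    ggplot2::scale_y_reverse(breaks = unique(nd$y)) +
    ggplot2::labs(x = NULL, y = "principal component", colour = NULL) +
    ggplot2::theme_minimal()
}
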