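#' Construct a feature table
#'
#' A feature table is a wide tibble holding a sample-by-feature microbial
#' abundance matrix: the first column, `sample_id`, identifies samples and
#' every remaining column is one feature (taxon, gene family, ...) of
#' non-negative abundances. Counts and relative abundances are both
#' supported; the `is_relative` attribute records which one the table holds,
#' and relative tables must have rows summing to one.
#'
#' @param x A data frame whose first column holds unique sample identifiers
#'   and whose remaining columns are numeric, or a numeric matrix
#'   (samples in rows) with row and column names.
#' @param is_relative Logical; `TRUE` when the values are relative abundances
#'   (each row sums to 1), `FALSE` (default) for counts or other
#'   unconstrained non-negative values.
#'
#' @return A tibble of class `feature_tbl` with a `sample_id` column followed
#'   by one numeric column per feature.
#' @export
#' @examples
#' feature_table(data.frame(sample_id = c("s1", "s2"), taxA = c(3, 0), taxB = c(1, 2)))
feature_table <- function(x, is_relative = FALSE) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input requires row (sample) and column (feature) names", call. = FALSE)
    }
    rn <- rownames(x)
    rownames(x) <- NULL
    x <- dplyr::bind_cols(
      tibble::tibble(sample_id = rn),
      tibble::as_tibble(as.data.frame(x, check.names = FALSE))
    )
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) stop("feature table needs a sample column and >= 1 feature", call. = FALSE)
  names(x)[1L] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id values", call. = FALSE)
  if (anyDuplicated(names(x)[-1L])) stop("duplicated feature ids", call. = FALSE)
  vals <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("feature columns must be numeric", call. = FALSE)
  if (anyNA(vals)) stop("feature table contains missing values", call. = FALSE)
  if (any(vals < 0)) stop("feature table contains negative values", call. = FALSE)
  if (isTRUE(is_relative)) {
    rs <- rowSums(vals)
    if (any(abs(rs - 1) > 1e-8)) {
      stop("is_relative = TRUE but row sums deviate from 1", call. = FALSE)
    }
  }
  structure(x,
    class = c("feature_tbl", class(tibble::tibble())),
    is_relative = isTRUE(is_relative)
  )
}

#' @export
print.feature_tbl <- function(x, ...) {
  cat(
    "# Feature table: ", nrow(x), " samples x ", ncol(x) - 1L, " features (",
    if (is_relative(x)) "relative abundances" else "counts", ")\n",
    sep = ""
  )
  NextMethod()
}

#' Extract the abundance matrix of a feature table
#'
#' @param t A [feature_table()].
#' @return Numeric samples-by-features matrix with sample ids as row names.
#' @export
ft_values <- function(t) {
  stopifnot(inherits(t, "feature_tbl") || (is.data.frame(t) && names(t)[1] == "sample_id"))
  m <- as.matrix(t[, -1L, drop = FALSE])
  rownames(m) <- t[["sample_id"]]
  m
}

#' @rdname feature_table
#' @export
is_relative <- function(x) isTRUE(attr(x, "is_relative"))

#' Read / write feature tables as TSV
#'
#' Reads a tab-separated abundance table with one header row and identifier
#' first column. Tables oriented features-in-rows (the common OTU-table
#' export, including the classic BIOM TSV dump whose header cell is
#' `#OTU ID`) are transposed to the internal samples-by-features layout.
#'
#' @param path File path.
#' @param orientation `"samples"` when rows are samples (default) or
#'   `"features"` when rows are features and columns samples.
#' @param is_relative Passed to [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, orientation = c("samples", "features"),
                               is_relative = FALSE) {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "# ") && !startsWith(first, "#OTU")) skip <- 1L
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE, skip = skip, comment.char = ""
  )
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "features") m <- t(m)
  feature_table(m, is_relative = is_relative)
}

#' @rdname read_feature_table
#' @param t A [feature_table()] to write.
#' @export
write_feature_table <- function(t, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(unclass(t), check.names = FALSE)), path)
  invisible(path)
}

#' Total-sum scaling (TSS) normalization
#'
#' Divides each sample row by its total so rows sum to one, yielding relative
#' abundances. Idempotent.
#'
#' @param t A [feature_table()]; every row must have a positive total.
#' @return A relative-abundance `feature_tbl`.
#' @export
tss_normalize <- function(t) {
  m <- ft_values(t)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop("all-zero sample row(s): ", paste(rownames(m)[rs <= 0], collapse = ", "), call. = FALSE)
  }
  feature_table(m / rs, is_relative = TRUE)
}

#' Arcsine square-root transformation
#'
#' The variance-stabilizing transform `asin(sqrt(p))` applied elementwise to
#' relative abundances, the standard transform for linear modelling of
#' proportions in community profiles. Output values lie in `[0, pi/2]`.
#'
#' @param t A relative-abundance [feature_table()], or a numeric matrix of
#'   proportions in `[0, 1]`.
#' @return Numeric samples-by-features matrix.
#' @export
arcsin_sqrt <- function(t) {
  m <- if (is.matrix(t)) t else ft_values(t)
  if (!is.matrix(t) && !is_relative(t)) {
    stop("arcsin_sqrt expects relative abundances; call tss_normalize() first", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) stop("values outside [0, 1]", call. = FALSE)
  asin(sqrt(m))
}

#' Abundance / prevalence / read-depth quality control
#'
#' Removes low-depth samples (total count strictly below `min_depth`), then
#' keeps features whose within-study relative abundance exceeds `min_abund`
#' in at least a fraction `min_prev` of the samples of at least one study.
#' Feature and sample order is preserved.
#'
#' @param t A count [feature_table()].
#' @param studies Character or factor vector of per-sample study labels,
#'   aligned with the rows of `t`.
#' @param min_abund Relative-abundance threshold a sample must strictly
#'   exceed to count as "present" (default `5e-5`).
#' @param min_prev Minimum within-study fraction of present samples
#'   (default `0.10`, compared with `>=`).
#' @param min_depth Minimum total count per sample (default `3000`; samples
#'   with depth strictly below are dropped).
#' @return The filtered `feature_tbl`.
#' @export
filter_quality <- function(t, studies, min_abund = 5e-5, min_prev = 0.10,
                           min_depth = 3000) {
  if (is_relative(t)) stop("filter_quality expects counts", call. = FALSE)
  m <- ft_values(t)
  studies <- as.character(studies)
  stopifnot(length(studies) == nrow(m))
  depth <- rowSums(m)
  keep_s <- depth >= min_depth
  if (!any(keep_s)) stop("all samples removed by the depth filter", call. = FALSE)
  m <- m[keep_s, , drop = FALSE]
  studies <- studies[keep_s]
  rel <- m / rowSums(m)
  keep_f <- rep(FALSE, ncol(m))
  for (s in unique(studies)) {
    rs <- rel[studies == s, , drop = FALSE]
    prev <- colMeans(rs > min_abund)
    keep_f <- keep_f | prev >= min_prev
  }
  if (!any(keep_f)) stop("all features removed by the abundance/prevalence filter", call. = FALSE)
  feature_table(m[, keep_f, drop = FALSE], is_relative = FALSE)
}

#' Aggregate features to a taxonomic rank
#'
#' Sums feature abundances by lineage truncated at `rank`. Features without a
#' classification at `rank` accumulate into an `"<deepest classified parent>
#' unclassified"` feature, so per-sample totals are conserved exactly.
#'
#' @param t A [feature_table()].
#' @param taxonomy Data frame with a `feature_id` column and ordered rank
#'   columns (e.g. `kingdom` ... `genus`); `NA` or `""` marks an absent rank.
#'   Every feature of `t` must be present.
#' @param rank Name of the rank column to aggregate at.
#' @return Aggregated `feature_tbl`.
#' @export
aggregate_taxonomy <- function(t, taxonomy, rank) {
  m <- ft_values(t)
  if (!rank %in% names(taxonomy)) stop("rank ", rank, " not in taxonomy", call. = FALSE)
  idx <- match(colnames(m), taxonomy$feature_id)
  if (anyNA(idx)) {
    stop(
      "features missing from taxonomy: ",
      paste(colnames(m)[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  ranks <- setdiff(names(taxonomy), "feature_id")
  r_i <- match(rank, ranks)
  lab <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    lin <- as.character(taxonomy[idx[j], ranks, drop = TRUE])
    lin[lin == ""] <- NA_character_
    if (!is.na(lin[r_i])) {
      lab[j] <- lin[r_i]
    } else {
      parent <- rev(lin[seq_len(r_i - 1L)])
      parent <- parent[!is.na(parent)][1L]
      if (is.na(parent) || length(parent) == 0L) parent <- "root"
      lab[j] <- paste(parent, "unclassified")
    }
  }
  groups <- unique(lab)
  agg <- vapply(
    groups,
    function(g) rowSums(m[, lab == g, drop = FALSE]),
    numeric(nrow(m))
  )
  if (nrow(m) == 1L) agg <- matrix(agg, nrow = 1L, dimnames = list(rownames(m), groups))
  feature_table(agg, is_relative = is_relative(t))
}

#' Community dissimilarity matrices
#'
#' Computes a symmetric sample-by-sample dissimilarity matrix. `"bray"` is
#' Bray-Curtis, `1 - 2 * sum(min(x, y)) / sum(x + y)`; `"jaccard"` is the
#' presence/absence Jaccard distance `1 - |A n B| / |A u B|`; `"rjsd"` is the
#' root Jensen-Shannon divergence on relative abundances (natural logarithm,
#' `0 * log 0 = 0`).
#'
#' @param t A [feature_table()] (or numeric matrix) of non-negative values;
#'   no row may be all zero. `"rjsd"` renormalizes rows internally.
#' @param method One of `"bray"`, `"jaccard"`, `"rjsd"`.
#' @return Symmetric numeric matrix with zero diagonal and sample-id dimnames.
#' @export
dissimilarity <- function(t, method = c("bray", "jaccard", "rjsd")) {
  method <- match.arg(method)
  m <- if (is.matrix(t)) t else ft_values(t)
  if (any(rowSums(m) == 0)) stop("all-zero sample row", call. = FALSE)
  d <- switch(method,
    bray = vegan::vegdist(m, method = "bray"),
    jaccard = vegan::vegdist(m, method = "jaccard", binary = TRUE),
    rjsd = rjsd_dist(m / rowSums(m))
  )
  out <- as.matrix(d)
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' @rdname dissimilarity
#' @export
bray_curtis <- function(t) dissimilarity(t, "bray")

# root Jensen-Shannon divergence on a row-stochastic matrix
rjsd_dist <- function(p) {
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  h <- rowSums(xlogx(p)) # negative entropy per sample
  n <- nrow(p)
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    pa <- p[a, ]
    for (b in (a + 1L):n) {
      mix <- (pa + p[b, ]) / 2
      jsd <- (h[a] + h[b]) / 2 - sum(xlogx(mix))
      d[a, b] <- d[b, a] <- sqrt(max(jsd, 0))
    }
  }
  stats::as.dist(d)
}
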