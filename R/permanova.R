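#' Marginal PERMANOVA with blocked permutations
#'
#' Partitions a dissimilarity matrix's (Gower-centered) sum of squares by a
#' single metadata variable and reports the variance explained `R2`, the
#' pseudo-F statistic, and a permutation p-value. The variable is tested
#' marginally (the sole term in the model); conditioning on another variable
#' is expressed by restricting the test to a sample `subset` before testing.
#'
#' Three permutation schemes cover the repeated-measures designs that arise
#' in multi-study collections: `"free"` permutes samples without
#' restriction; `"within"` permutes values within each block (per-sample
#' variables measured repeatedly on a subject); `"blocks"` permutes whole
#' blocks and requires equal block sizes (per-subject variables carried by
#' all of a subject's samples).
#'
#' @param d Symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param meta Data frame of per-sample metadata aligned with `d`.
#' @param variable Name of the metadata column to test; must be
#'   non-constant.
#' @param n_perm Number of permutations (default `2000`); `0` skips the
#'   permutation test and returns `p = NA` (the `R2` needs none).
#' @param blocks Optional name of a block (e.g. subject) column, required
#'   for the `"within"` and `"blocks"` schemes.
#' @param scheme Permutation scheme, see Details.
#' @param subset Optional logical or integer index restricting samples
#'   before testing.
#' @param seed Optional integer seed for the permutations.
#' @return A one-row tibble: `variable`, `r2`, `f`, `p`, `n_perm`, `scheme`,
#'   `n` (samples used). The permutation p-value is `(count + 1) /
#'   (n_perm + 1)`, never exactly zero.
#' @export
permanova_r2 <- function(d, meta, variable, n_perm = 2000, blocks = NULL,
                         scheme = c("free", "within", "blocks"),
                         subset = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), nrow(d) == nrow(meta))
  if (!is.null(subset)) {
    d <- d[subset, subset, drop = FALSE]
    meta <- meta[subset, , drop = FALSE]
  }
  v <- meta[[variable]]
  if (is.null(v)) stop("no metadata column '", variable, "'", call. = FALSE)
  if (length(unique(v)) < 2L) stop("variable '", variable, "' is constant", call. = FALSE)
  n <- nrow(d)
  df <- data.frame(.v = v)
  dd <- stats::as.dist(d)

  if (n_perm > 0) {
    if (!is.null(seed)) {
      state <- local_seed(seed)
      on.exit(restore_seed(state), add = TRUE)
    }
    ctrl <- switch(scheme,
      free = permute::how(nperm = n_perm),
      within = {
        if (is.null(blocks)) stop("scheme 'within' needs blocks", call. = FALSE)
        permute::how(nperm = n_perm, blocks = factor(meta[[blocks]]))
      },
      blocks = {
        if (is.null(blocks)) stop("scheme 'blocks' needs blocks", call. = FALSE)
        permute::how(
          nperm = n_perm,
          plots = permute::Plots(strata = factor(meta[[blocks]]), type = "free"),
          within = permute::Within(type = "none")
        )
      }
    )
    fit <- vegan::adonis2(dd ~ .v, data = df, permutations = ctrl, by = "terms")
    p <- fit$`Pr(>F)`[1L]
  } else {
    fit <- vegan::adonis2(dd ~ .v,
      data = df, by = "terms",
      permutations = matrix(seq_len(n), nrow = 1L)
    )
    p <- NA_real_
  }
  tibble::tibble(
    variable = variable, r2 = fit$R2[1L], f = fit$F[1L], p = p,
    n_perm = n_perm, scheme = scheme, n = n
  )
}

#' False-positive rate at a nominal level
#'
#' The fraction of p-values below `alpha` — on null data, the empirical
#' false-positive rate of a test.
#'
#' @param pvals Numeric vector of p-values (NAs dropped).
#' @param alpha Nominal level (default `0.05`).
#' @return A single number in `[0, 1]`.
#' @export
false_positive_rate <- function(pvals, alpha = 0.05) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) return(NA_real_)
  mean(pvals < alpha)
}

#' Structure-recovery scores against simulated truth
#'
#' For discrete designs, the success indicator that the selected number of
#' clusters equals the simulated one; for continuous designs, the absolute
#' Pearson and Spearman correlations between an assigned score and the
#' simulated gradient (sign-invariant, since gradients are identified only
#' up to sign).
#'
#' @param truth True cluster number (scalar) or gradient (numeric vector).
#' @param estimate Selected cluster number(s) or assigned score vector.
#' @return For clusters, the success fraction; for gradients, a one-row
#'   tibble with `pearson` and `spearman` absolute correlations.
#' @export
recovery_metrics <- function(truth, estimate) {
  if (length(truth) == 1L) {
    return(mean(estimate == truth))
  }
  stopifnot(length(truth) == length(estimate))
  tibble::tibble(
    pearson = abs(stats::cor(estimate, truth, method = "pearson")),
    spearman = abs(stats::cor(estimate, truth, method = "spearman"))
  )
}
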