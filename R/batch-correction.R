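#' Zero-inflated, covariate-adjusted batch correction of count profiles
#'
#' Batch (or study) effects on microbial count profiles are modelled
#' feature-wise on the log scale of the non-zero counts:
#' `Y = exp(beta' X + sigma * (gamma_i + delta_i * eps)) * I`, where `I` is
#' the zero indicator, `X` holds the intercept and biological covariates,
#' `sigma` is a feature-wise standardization factor and `(gamma_i, delta_i)`
#' are batch-specific location and scale parameters. The parameters are
#' estimated on non-zero counts only, the batch parameters are shrunken by
#' parametric empirical Bayes (normal prior on locations, inverse-gamma on
#' squared scales, hyperparameters by method of moments across features),
#' and the correction removes the shrunken batch location/scale from every
#' non-zero count:
#' `log Y' = (log Y - beta' X - gamma* sigma) / delta* + beta' X`.
#' Zero counts are never touched (presence/absence is preserved), and each
#' corrected sample is rescaled to its original read depth.
#'
#' `correct_batch()` runs the three stages ([fit_standardization()],
#' [eb_shrink()], [apply_correction()]) in order and is the function most
#' analyses need.
#'
#' @param t A count [feature_table()] (relative abundances are accepted;
#'   they are treated as depth-1 counts and re-closed after correction).
#' @param meta Data frame of per-sample metadata aligned with `t`.
#' @param batch Name of the batch column (factor-like, `>= 2` levels, every
#'   level with `>= 2` samples).
#' @param covariates Character vector of biological covariate columns whose
#'   effects must be retained through correction (categoricals are
#'   reference-dummy coded, continuous used as-is).
#' @param eb If `FALSE`, empirical-Bayes shrinkage is disabled and the
#'   frequentist per-batch estimates are used directly.
#' @param min_nonzero Minimum non-zero observations a batch-feature pair
#'   needs for its parameters to be estimated (default `2`); pairs below it
#'   are left uncorrected (`gamma* = 0`, `delta* = 1`).
#' @return `correct_batch()`: the corrected `feature_tbl`, with the fitted
#'   model in attribute `"fit"`.
#' @seealso [tidy.batch_correction_fit()] for the per-batch-feature
#'   parameter table.
#' @export
correct_batch <- function(t, meta, batch = "batch", covariates = NULL,
                          eb = TRUE, min_nonzero = 2) {
  fit <- fit_standardization(t, meta,
    batch = batch, covariates = covariates,
    min_nonzero = min_nonzero
  )
  fit <- eb_shrink(fit, shrink = eb)
  out <- apply_correction(t, fit)
  attr(out, "fit") <- fit
  out
}

#' @rdname correct_batch
#' @param sigma_floor Lower bound on the feature standardization factor.
#' @return `fit_standardization()`: an object of class
#'   `batch_correction_fit` holding the frequentist estimates (`beta`,
#'   `sigma`, per-batch `gamma_hat`/`delta_hat`, the zero mask and
#'   per-batch-feature non-zero counts).
#' @export
fit_standardization <- function(t, meta, batch = "batch", covariates = NULL,
                                min_nonzero = 2, sigma_floor = 1e-8) {
  m <- ft_values(t)
  stopifnot(nrow(meta) == nrow(m))
  b <- factor(meta[[batch]])
  if (is.null(meta[[batch]])) stop("no metadata column '", batch, "'", call. = FALSE)
  b <- droplevels(b)
  if (nlevels(b) < 2L) stop("need >= 2 batches; nothing to correct", call. = FALSE)
  if (any(table(b) < 2L)) {
    stop(
      "batch level(s) with < 2 samples: ",
      paste(names(which(table(b) < 2L)), collapse = ", "),
      call. = FALSE
    )
  }
  covariates <- covariates %||% character(0)
  if (length(covariates)) {
    cov_df <- as.data.frame(meta[, covariates, drop = FALSE])
    # non-numeric missingness becomes an explicit level; numeric NA is refused
    for (j in seq_along(cov_df)) {
      if (is.character(cov_df[[j]]) || is.factor(cov_df[[j]])) {
        cv <- as.character(cov_df[[j]])
        cv[is.na(cv)] <- "missing"
        cov_df[[j]] <- factor(cv)
      } else if (anyNA(cov_df[[j]])) {
        stop("missing values in continuous covariate '", covariates[j], "'", call. = FALSE)
      }
    }
    Xc <- stats::model.matrix(~., data = cov_df)[, -1L, drop = FALSE]
  } else {
    Xc <- matrix(0, nrow(m), 0L)
  }
  Xb <- stats::model.matrix(~ 0 + b) # batch cell means
  X <- cbind(Xb, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(
      "design is rank deficient (covariates confounded with batch): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }

  n <- nrow(m)
  P <- ncol(m)
  B <- nlevels(b)
  zero_mask <- m == 0
  n_nz <- matrix(0L, B, P, dimnames = list(levels(b), colnames(m)))
  alpha <- numeric(P)
  sigma <- numeric(P)
  cov_coef <- matrix(0, ncol(Xc), P, dimnames = list(colnames(Xc), colnames(m)))
  gamma_hat <- matrix(NA_real_, B, P, dimnames = dimnames(n_nz))
  delta_hat <- matrix(NA_real_, B, P, dimnames = dimnames(n_nz))
  Z <- matrix(NA_real_, n, P, dimnames = dimnames(m))
  uncorrectable <- logical(P)

  for (p in seq_len(P)) {
    idx <- which(!zero_mask[, p])
    n_nz[, p] <- tabulate(b[idx], nbins = B)
    if (length(idx) < 2L) {
      uncorrectable[p] <- TRUE
      sigma[p] <- sigma_floor
      next
    }
    ly <- log(m[idx, p])
    bp <- droplevels(b[idx])
    Xb_p <- vapply(levels(bp), function(l) as.numeric(bp == l), numeric(length(idx)))
    Xp <- cbind(Xb_p, Xc[idx, , drop = FALSE])
    f <- stats::lm.fit(Xp, ly)
    coefs <- f$coefficients
    coefs[is.na(coefs)] <- 0 # aliased columns (e.g. covariate constant here)
    nb <- ncol(Xb_p)
    batch_means <- coefs[seq_len(nb)]
    w <- table(bp) / length(idx)
    alpha[p] <- sum(w * batch_means)
    if (ncol(Xc)) cov_coef[, p] <- coefs[-seq_len(nb)]
    fitted <- drop(Xp %*% coefs)
    sigma[p] <- max(sqrt(mean((ly - fitted)^2)), sigma_floor)
    stand <- alpha[p] + if (ncol(Xc)) drop(Xc[idx, , drop = FALSE] %*% cov_coef[, p]) else 0
    Z[idx, p] <- (ly - stand) / sigma[p]
    for (i in which(n_nz[, p] > 0L)) {
      zi <- Z[idx, p][b[idx] == levels(b)[i]]
      gamma_hat[i, p] <- mean(zi)
      delta_hat[i, p] <- if (length(zi) >= 2L) stats::sd(zi) else NA_real_
    }
  }

  estimable <- sweep(n_nz >= min_nonzero, 2L, !uncorrectable, "&")

  structure(
    list(
      feature_ids = colnames(m), batch = b, batch_levels = levels(b),
      covariates = covariates, cov_design = Xc, cov_coef = cov_coef,
      alpha = alpha, sigma = sigma, Z = Z,
      gamma_hat = gamma_hat, delta_hat = delta_hat,
      gamma_star = NULL, delta_star = NULL,
      n_nz = n_nz, estimable = estimable, uncorrectable = uncorrectable,
      zero_mask = zero_mask, min_nonzero = min_nonzero,
      hyper = NULL, shrunk = FALSE
    ),
    class = "batch_correction_fit"
  )
}

#' @rdname correct_batch
#' @param fit A `batch_correction_fit` from [fit_standardization()].
#' @param shrink If `FALSE`, shrinkage is a no-op (frequentist estimates
#'   are copied to the shrunken slots).
#' @param tol Convergence tolerance of the iterative conditional posterior
#'   update (maximum absolute relative change, default `1e-4`).
#' @param max_iter Iteration cap (default `500`).
#' @return `eb_shrink()`: the fit with shrunken `gamma_star` / `delta_star`
#'   (a scale, always positive) and the per-batch prior hyperparameters.
#' @export
eb_shrink <- function(fit, shrink = TRUE, tol = 1e-4, max_iter = 500) {
  stopifnot(inherits(fit, "batch_correction_fit"))
  B <- length(fit$batch_levels)
  P <- length(fit$feature_ids)
  gamma_star <- matrix(0, B, P, dimnames = dimnames(fit$gamma_hat))
  delta_star <- matrix(1, B, P, dimnames = dimnames(fit$gamma_hat))
  hyper <- vector("list", B)
  names(hyper) <- fit$batch_levels

  for (i in seq_len(B)) {
    ok <- which(fit$estimable[i, ] & !is.na(fit$delta_hat[i, ]))
    if (!length(ok)) next
    g <- fit$gamma_hat[i, ok]
    d2 <- fit$delta_hat[i, ok]^2
    if (!shrink || length(ok) < 3L) {
      if (shrink && length(ok) < 3L) {
        warning(
          "batch ", fit$batch_levels[i], ": < 3 estimable features; ",
          "shrinkage skipped (frequentist estimates used)",
          call. = FALSE
        )
      }
      gamma_star[i, ok] <- g
      delta_star[i, ok] <- pmax(sqrt(d2), 1e-8)
      next
    }
    g_bar <- mean(g)
    t2 <- max(stats::var(g), 1e-12)
    m_d <- mean(d2)
    s2_d <- stats::var(d2)
    if (s2_d < 1e-12) {
      # degenerate scale spread: no information to shrink scales with
      a_pr <- Inf
      b_pr <- Inf
    } else {
      a_pr <- (2 * s2_d + m_d^2) / s2_d
      b_pr <- (m_d * s2_d + m_d^3) / s2_d
    }
    hyper[[i]] <- list(gamma_bar = g_bar, tau2 = t2, a_prior = a_pr, b_prior = b_pr)

    n_i <- fit$n_nz[i, ok]
    in_batch <- fit$batch == fit$batch_levels[i]
    Zi <- fit$Z[in_batch, ok, drop = FALSE]
    g_old <- g
    d_old <- d2
    for (iter in seq_len(max_iter)) {
      g_new <- (n_i * t2 * g + d_old * g_bar) / (n_i * t2 + d_old)
      sum2 <- colSums(sweep(Zi, 2L, g_new, "-")^2, na.rm = TRUE)
      d_new <- if (is.finite(a_pr)) {
        (0.5 * sum2 + b_pr) / (n_i / 2 + a_pr - 1)
      } else {
        d2
      }
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
        abs(d_new - d_old) / (abs(d_old) + 1e-12),
        na.rm = TRUE
      )
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    gamma_star[i, ok] <- g_old
    delta_star[i, ok] <- sqrt(pmax(d_old, 1e-12))
  }

  fit$gamma_star <- gamma_star
  fit$delta_star <- delta_star
  fit$hyper <- hyper
  fit$shrunk <- shrink
  fit
}

#' @rdname correct_batch
#' @return `apply_correction()`: the corrected `feature_tbl`; zero entries
#'   are exactly preserved and per-sample totals match the input to
#'   `1e-8` relative.
#' @export
apply_correction <- function(t, fit) {
  stopifnot(inherits(fit, "batch_correction_fit"))
  if (is.null(fit$gamma_star)) stop("run eb_shrink() before apply_correction()", call. = FALSE)
  m <- ft_values(t)
  if (!identical(colnames(m), fit$feature_ids)) {
    stop("feature ids of table and fit differ", call. = FALSE)
  }
  stopifnot(nrow(m) == length(fit$batch))
  bi <- as.integer(fit$batch)
  stand <- matrix(fit$alpha, nrow(m), ncol(m), byrow = TRUE)
  if (ncol(fit$cov_design)) stand <- stand + fit$cov_design %*% fit$cov_coef
  sig <- matrix(fit$sigma, nrow(m), ncol(m), byrow = TRUE)
  gs <- fit$gamma_star[bi, , drop = FALSE]
  ds <- fit$delta_star[bi, , drop = FALSE]
  totals <- rowSums(m)
  nz <- m > 0
  lm_ <- matrix(NA_real_, nrow(m), ncol(m))
  lm_[nz] <- log(m[nz])
  adj <- (lm_ - stand - gs * sig) / ds + stand
  out <- m
  out[nz] <- exp(adj[nz])
  new_tot <- rowSums(out)
  scale <- ifelse(new_tot > 0, totals / new_tot, 1)
  out <- out * scale
  res <- feature_table(out, is_relative = FALSE)
  attr(res, "is_relative") <- is_relative(t)
  res
}

#' @export
print.batch_correction_fit <- function(x, ...) {
  cat(
    "# Batch-correction fit: ", length(x$feature_ids), " features, ",
    length(x$batch_levels), " batches",
    if (x$shrunk) " (empirical-Bayes shrunken)\n" else " (not yet shrunken)\n",
    sep = ""
  )
  cat(
    "#   uncorrectable features: ", sum(x$uncorrectable),
    "; batch-feature pairs below min_nonzero: ",
    sum(!x$estimable & !is.na(x$gamma_hat)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a batch-correction fit
#'
#' One row per batch-feature pair: frequentist and shrunken location/scale
#' estimates, the non-zero count behind them, and whether the pair was
#' corrected.
#'
#' @param x A `batch_correction_fit`.
#' @param ... Unused.
#' @return A tibble with columns `batch`, `feature_id`, `n_nonzero`,
#'   `gamma_hat`, `delta_hat`, `gamma_star`, `delta_star`, `corrected`.
#' @export
tidy.batch_correction_fit <- function(x, ...) {
  B <- length(x$batch_levels)
  P <- length(x$feature_ids)
  tibble::tibble(
    batch = rep(x$batch_levels, times = P),
    feature_id = rep(x$feature_ids, each = B),
    n_nonzero = as.vector(x$n_nz),
    gamma_hat = as.vector(x$gamma_hat),
    delta_hat = as.vector(x$delta_hat),
    gamma_star = if (is.null(x$gamma_star)) NA_real_ else as.vector(x$gamma_star),
    delta_star = if (is.null(x$delta_star)) NA_real_ else as.vector(x$delta_star),
    corrected = as.vector(x$estimable)
  )
}

#' @rdname tidy.batch_correction_fit
#' @return `glance()`: a one-row tibble summarizing the fit.
#' @export
glance.batch_correction_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_ids),
    n_batches = length(x$batch_levels),
    n_covariate_columns = ncol(x$cov_design),
    n_uncorrectable = sum(x$uncorrectable),
    n_pairs_uncorrected = sum(!x$estimable),
    shrunken = x$shrunk
  )
}

#' Plot shrinkage of per-batch location parameters
#'
#' Frequentist versus empirical-Bayes-shrunken batch location estimates, one
#' panel per batch; points on the diagonal were not shrunken.
#'
#' @param object A shrunken `batch_correction_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.batch_correction_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$corrected, ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$gamma_hat, y = .data$gamma_star)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~batch) +
    ggplot2::labs(
      x = "frequentist batch location",
      y = "shrunken batch location"
    ) +
    ggplot2::theme_minimal()
}
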