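#' Per-study differential-abundance models
#'
#' Fits, within one study, a linear model of arcsine-square-root transformed
#' relative abundance on an exposure plus covariates, feature by feature,
#' returning the exposure effect and its standard error. With a
#' `random_group` column and repeated measures (any group with two or more
#' samples) a random-intercept linear mixed model (REML) is used instead.
#' Features absent (all zero) in the study, or whose effect is inestimable,
#' are reported with status `"absent"` rather than a zero effect.
#'
#' @param t A [feature_table()] for the study (counts or relative; TSS and
#'   arcsine-square-root transforms are applied internally).
#' @param meta Per-sample metadata aligned with `t`.
#' @param exposure Name of the exposure column: binary factor-like or
#'   continuous, and non-constant within the study.
#' @param covariates Optional character vector of adjustment covariates.
#' @param random_group Optional subject/grouping column for repeated
#'   measures.
#' @return A tibble with one row per feature: `feature_id`, `effect`
#'   (exposure coefficient on the transformed scale), `se`, `n_used`,
#'   `model` (`"lm"` or `"lmm"`), `status` (`"ok"` or `"absent"`).
#' @export
fit_study_model <- function(t, meta, exposure, covariates = NULL,
                            random_group = NULL) {
  m <- ft_values(t)
  stopifnot(nrow(meta) == nrow(m))
  v <- meta[[exposure]]
  if (is.null(v)) stop("no metadata column '", exposure, "'", call. = FALSE)
  if (length(unique(v)) < 2L) {
    return(tibble::tibble(
      feature_id = colnames(m), effect = NA_real_, se = NA_real_,
      n_used = 0L, model = NA_character_, status = "absent"
    ))
  }
  y <- transformed_abundance(t)
  covariates <- covariates %||% character(0)
  df <- as.data.frame(meta[, c(exposure, covariates), drop = FALSE])
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  rhs <- paste(c(sprintf("`%s`", exposure), sprintf("`%s`", covariates)), collapse = " + ")

  use_lmm <- FALSE
  if (!is.null(random_group)) {
    g <- meta[[random_group]]
    if (is.null(g)) stop("no metadata column '", random_group, "'", call. = FALSE)
    use_lmm <- any(table(g) >= 2L)
    df$.grp <- factor(g)
  }

  absent <- colSums(ft_values(t) > 0) == 0L
  exposure_term <- function(X) {
    cols <- which(attr(X, "assign") == 1L)
    if (!length(cols)) stop("exposure dropped from design", call. = FALSE)
    cols[1L] # binary/continuous exposure: single coefficient
  }

  if (!use_lmm) {
    X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
    if (qr(X)$rank < ncol(X)) {
      qrX <- qr(X)
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("singular design: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    term <- exposure_term(X)
    f <- stats::lm.fit(X, y)
    coefs <- f$coefficients[term, ]
    rss <- colSums(f$residuals^2)
    dfres <- nrow(X) - ncol(X)
    xtxi <- chol2inv(chol(crossprod(X)))[term, term]
    se <- sqrt(pmax(rss, 0) / dfres * xtxi)
    out <- tibble::tibble(
      feature_id = colnames(m), effect = unname(coefs), se = unname(se),
      n_used = nrow(X), model = "lm", status = "ok"
    )
  } else {
    form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .grp)"))
    res <- purrr::map(seq_len(ncol(y)), function(p) {
      d2 <- df
      d2$.y <- y[, p]
      fit <- tryCatch(
        suppressMessages(suppressWarnings(lme4::lmer(form, data = d2, REML = TRUE))),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(c(NA_real_, NA_real_))
      }
      cf <- summary(fit)$coefficients
      X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
      nm <- colnames(X)[exposure_term(X)]
      c(cf[nm, "Estimate"], cf[nm, "Std. Error"])
    })
    res <- do.call(rbind, res)
    out <- tibble::tibble(
      feature_id = colnames(m), effect = res[, 1L], se = res[, 2L],
      n_used = nrow(y), model = "lmm", status = "ok"
    )
  }
  bad <- absent | !is.finite(out$effect) | !is.finite(out$se) | out$se <= 0
  out$status[bad] <- "absent"
  out$effect[bad] <- NA_real_
  out$se[bad] <- NA_real_
  out
}

# TSS + arcsin-sqrt, tolerating tables that are already relative
transformed_abundance <- function(t) {
  if (is_relative(t)) arcsin_sqrt(t) else arcsin_sqrt(tss_normalize(t))
}

#' Pool per-study effects by fixed- or random-effects meta-analysis
#'
#' Inverse-variance pooling of one feature's per-study effects. The
#' random-effects model estimates the between-study variance `tau2` by
#' restricted maximum likelihood (falling back to DerSimonian-Laird when
#' REML does not converge); the fixed-effect model sets `tau2 = 0`.
#'
#' @param effects Tibble with one row per study: columns `effect` and `se`
#'   (rows with missing values are dropped).
#' @param method `"random"` (REML, default) or `"fixed"`.
#' @return One-row tibble: `beta` (pooled effect), `se`, `tau2`, `z`, `p`
#'   (two-sided normal), `k` (studies used), and a `weights` list-column of
#'   normalized per-study weights.
#' @export
pool_effects <- function(effects, method = c("random", "fixed")) {
  method <- match.arg(method)
  ok <- is.finite(effects$effect) & is.finite(effects$se) & effects$se > 0
  eff <- effects[ok, , drop = FALSE]
  if (!nrow(eff)) {
    return(tibble::tibble(
      beta = NA_real_, se = NA_real_, tau2 = NA_real_, z = NA_real_,
      p = NA_real_, k = 0L, weights = list(numeric(0))
    ))
  }
  mmethod <- if (method == "fixed") "FE" else "REML"
  fit <- tryCatch(
    metafor::rma.uni(
      yi = eff$effect, sei = eff$se, method = mmethod,
      control = list(maxiter = 100)
    ),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(fit)) {
    fit <- metafor::rma.uni(yi = eff$effect, sei = eff$se, method = "DL")
  }
  w <- stats::weights(fit) / 100
  tibble::tibble(
    beta = as.numeric(fit$beta), se = fit$se,
    tau2 = if (mmethod == "FE") 0 else fit$tau2,
    z = fit$zval, p = fit$pval, k = fit$k,
    weights = list(stats::setNames(w, eff$study %||% seq_len(nrow(eff))))
  )
}

#' Meta-analysis moderator (interaction) model
#'
#' Regresses per-stratum effects on a binary stratum-level moderator with
#' random stratum effects (weighted meta-regression). The moderator
#' coefficient `beta1` is the interaction effect between the exposure
#' behind the per-stratum effects and the moderator.
#'
#' @param effects Tibble with columns `stratum`, `feature_id`, `effect`,
#'   `se` (one row per stratum and feature).
#' @param moderator Named logical/0-1 vector (or two-level factor) giving
#'   each stratum's moderator level, names matching `stratum`; both levels
#'   must be represented.
#' @return A tibble per feature: `feature_id`, `beta0`, `beta1`, `se1`,
#'   `p1`, `k`.
#' @export
moderator_test <- function(effects, moderator) {
  lv <- moderator[match(unique(effects$stratum), names(moderator))]
  if (length(unique(as.numeric(lv))) < 2L) {
    stop("moderator is constant across strata", call. = FALSE)
  }
  effects %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::group_modify(function(d, key) {
      ok <- is.finite(d$effect) & is.finite(d$se) & d$se > 0
      d <- d[ok, , drop = FALSE]
      mod <- as.numeric(moderator[match(d$stratum, names(moderator))])
      if (nrow(d) < 2L || length(unique(mod)) < 2L) {
        return(tibble::tibble(
          beta0 = NA_real_, beta1 = NA_real_,
          se1 = NA_real_, p1 = NA_real_, k = nrow(d)
        ))
      }
      fit <- tryCatch(
        metafor::rma.uni(
          yi = d$effect, sei = d$se, mods = ~mod, method = "REML",
          control = list(maxiter = 100)
        ),
        error = function(e) {
          tryCatch(
            metafor::rma.uni(yi = d$effect, sei = d$se, mods = ~mod, method = "DL"),
            # saturated design (one stratum per moderator level): no
            # residual information, heterogeneity fixed at zero
            error = function(e2) {
              metafor::rma.uni(yi = d$effect, sei = d$se, mods = ~mod, method = "FE")
            }
          )
        }
      )
      tibble::tibble(
        beta0 = as.numeric(fit$beta[1L]), beta1 = as.numeric(fit$beta[2L]),
        se1 = fit$se[2L], p1 = fit$pval[2L], k = nrow(d)
      )
    }) %>%
    dplyr::ungroup()
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (a thin wrapper over [stats::p.adjust()]; NAs are passed through).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Run a full meta-analysis of differential abundance
#'
#' Splits samples into per-study (optionally further stratified) units,
#' fits the per-study model ([fit_study_model()]) in each, pools the
#' exposure effects across units ([pool_effects()]), and adjusts pooled
#' p-values across features by Benjamini-Hochberg.
#'
#' @inheritParams fit_study_model
#' @param study Name of the study column.
#' @param strata Optional additional stratification column; analysis units
#'   are then study-by-stratum cells.
#' @param method Pooling model, `"random"` (default) or `"fixed"`.
#' @return An object of class `meta_da`: list with `pooled` (per-feature
#'   tibble `feature_id`, `beta`, `se`, `tau2`, `z`, `p`, `q`, `k`) and
#'   `per_study` (per-unit effects).
#' @export
run_meta_da <- function(t, meta, exposure, covariates = NULL, study = "study",
                        strata = NULL, random_group = NULL,
                        method = c("random", "fixed")) {
  method <- match.arg(method)
  m <- ft_values(t)
  stopifnot(nrow(meta) == nrow(m))
  unit <- as.character(meta[[study]])
  if (is.null(meta[[study]])) stop("no metadata column '", study, "'", call. = FALSE)
  if (!is.null(strata)) unit <- paste(unit, as.character(meta[[strata]]), sep = ":")

  per_study <- purrr::map_dfr(unique(unit), function(u) {
    idx <- unit == u
    sub <- feature_table(m[idx, , drop = FALSE], is_relative = is_relative(t))
    eff <- fit_study_model(sub, meta[idx, , drop = FALSE], exposure,
      covariates = covariates, random_group = random_group
    )
    eff$study <- u
    eff
  })

  pooled <- per_study %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::group_modify(~ pool_effects(.x, method = method)) %>%
    dplyr::ungroup()
  pooled <- pooled[match(colnames(m), pooled$feature_id), ]
  pooled$q <- bh_adjust(pooled$p)

  structure(
    list(
      pooled = pooled, per_study = per_study, exposure = exposure,
      method = method
    ),
    class = "meta_da"
  )
}

#' Pooled severity contrasts for an ordinal exposure
#'
#' For an ordinal exposure with levels `L1 < L2 < L3`, produces three pooled
#' effects per feature: the pairwise contrasts `L2 vs L1` and `L3 vs L1`
#' (each fit on the subset of samples at the two levels involved), and the
#' incremental top-level effect `beta2` from the joint model `~ I{L2 or L3}
#' + I{L3} + covariates`. FDR for the pairwise contrasts runs across all
#' features; FDR for `beta2` is restricted to features already significant
#' (at `sig_q`) in either pairwise contrast.
#'
#' @inheritParams run_meta_da
#' @param exposure Name of the ordinal exposure column; its first three
#'   factor levels are taken as `L1 < L2 < L3`.
#' @param sig_q Significance cutoff defining the `beta2` FDR pool
#'   (default `0.05`).
#' @return A tibble with one row per feature and contrast (`"L2_vs_L1"`,
#'   `"L3_vs_L1"`, `"L3_incremental"`): pooled `beta`, `se`, `tau2`, `p`,
#'   `q`, `k`.
#' @export
contrast_models <- function(t, meta, exposure, covariates = NULL,
                            study = "study", method = "random", sig_q = 0.05) {
  v <- factor(meta[[exposure]])
  if (nlevels(v) < 3L) stop("ordinal exposure needs >= 3 levels", call. = FALSE)
  lv <- levels(v)[1:3]
  m <- ft_values(t)

  fit_subset <- function(keep, meta2) {
    sub <- feature_table(m[keep, , drop = FALSE], is_relative = is_relative(t))
    run_meta_da(sub, meta2[keep, , drop = FALSE], ".contrast",
      covariates = covariates, study = study, method = method
    )$pooled
  }

  meta_a <- meta
  meta_a$.contrast <- as.numeric(v == lv[2])
  pa <- fit_subset(v %in% lv[c(1, 2)], meta_a)
  pa$contrast <- "L2_vs_L1"

  meta_b <- meta
  meta_b$.contrast <- as.numeric(v == lv[3])
  pb <- fit_subset(v %in% lv[c(1, 3)], meta_b)
  pb$contrast <- "L3_vs_L1"

  # joint model: beta2 = incremental L3 effect on top of the L23-vs-L1 shift
  meta_c <- meta
  meta_c$.contrast <- as.numeric(v == lv[3])
  meta_c$.l23 <- as.numeric(v %in% lv[c(2, 3)])
  sub <- feature_table(m[v %in% lv[1:3], , drop = FALSE], is_relative = is_relative(t))
  pc <- run_meta_da(sub, meta_c[v %in% lv[1:3], , drop = FALSE], ".contrast",
    covariates = c(".l23", covariates), study = study, method = method
  )$pooled
  pc$contrast <- "L3_incremental"
  pool <- pa$q <= sig_q | pb$q <= sig_q
  pool[is.na(pool)] <- FALSE
  pc$q <- NA_real_
  pc$q[pool] <- bh_adjust(pc$p[pool])

  dplyr::bind_rows(pa, pb, pc) %>%
    dplyr::select(
      "feature_id", "contrast", "beta", "se", "tau2", "p", "q", "k"
    )
}

#' @export
print.meta_da <- function(x, ...) {
  ns <- sum(x$pooled$q <= 0.05, na.rm = TRUE)
  cat(
    "# Meta-analysis of '", x$exposure, "' (", x$method, " effects): ",
    nrow(x$pooled), " features across ",
    length(unique(x$per_study$study)), " study units; ",
    ns, " at q <= 0.05\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy / summarize a meta-analysis result
#'
#' @param x A `meta_da` object from [run_meta_da()].
#' @param ... Unused.
#' @return `tidy()`: the pooled per-feature tibble. `glance()`: a one-row
#'   summary.
#' @export
tidy.meta_da <- function(x, ...) x$pooled

#' @rdname tidy.meta_da
#' @export
glance.meta_da <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, method = x$method,
    n_features = nrow(x$pooled),
    n_units = length(unique(x$per_study$study)),
    n_significant_q05 = sum(x$pooled$q <= 0.05, na.rm = TRUE),
    median_tau2 = stats::median(x$pooled$tau2, na.rm = TRUE)
  )
}

#' Volcano plot of pooled differential-abundance effects
#'
#' @param object A `meta_da` object.
#' @param q_cutoff Highlighting threshold on the BH q-value (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_da <- function(object, q_cutoff = 0.05, ...) {
  d <- object$pooled
  d$significant <- !is.na(d$q) & d$q <= q_cutoff
  ggplot2::ggplot(
    d[!is.na(d$p), ],
    ggplot2::aes(x = .data$beta, y = -log10(.data$p), colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "pooled effect (arcsin-sqrt scale)", y = "-log10 p",
      colour = paste0("q <= ", q_cutoff)
    ) +
    ggplot2::theme_minimal()
}
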