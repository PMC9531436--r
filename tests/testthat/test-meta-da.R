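test_that("per-study OLS matches the two-sample closed form", {
  set.seed(21)
  n <- 40
  g <- rep(c("control", "case"), each = n / 2)
  m <- matrix(stats::rlnorm(n * 3, 2, 0.4), n, 3,
    dimnames = list(paste0("s", 1:n), c("f1", "f2", "f3"))
  )
  t <- feature_table(m)
  meta <- tibble::tibble(sample_id = rownames(m), exposure = factor(g, c("control", "case")))
  eff <- fit_study_model(t, meta, "exposure")

  y <- arcsin_sqrt(tss_normalize(t))
  for (j in 1:3) {
    y1 <- y[g == "case", j]
    y0 <- y[g == "control", j]
    expect_equal(eff$effect[j], mean(y1) - mean(y0), tolerance = 1e-12)
    sp2 <- ((length(y0) - 1) * var(y0) + (length(y1) - 1) * var(y1)) / (n - 2)
    expect_equal(eff$se[j], sqrt(sp2 * (1 / length(y0) + 1 / length(y1))), tolerance = 1e-12)
  }

  # a feature proportional to the exposure indicator is fit exactly
  y2 <- cbind(m, marker = 1000 * (g == "case") + 1)
  t2 <- feature_table(y2)
  eff2 <- fit_study_model(t2, meta, "exposure")
  tr <- arcsin_sqrt(tss_normalize(t2))[, "marker"]
  expect_equal(
    eff2$effect[eff2$feature_id == "marker"],
    mean(tr[g == "case"]) - mean(tr[g == "control"]),
    tolerance = 1e-12
  )

  # constant exposure: everything is absent
  meta3 <- meta
  meta3$exposure <- factor("case")
  expect_true(all(fit_study_model(t, meta3, "exposure")$status == "absent"))

  # all-zero feature is absent, not zero
  m4 <- cbind(m, gone = 0)
  eff4 <- fit_study_model(feature_table(m4), meta, "exposure")
  expect_equal(eff4$status[eff4$feature_id == "gone"], "absent")
  expect_true(is.na(eff4$effect[eff4$feature_id == "gone"]))
})

test_that("random-intercept model is used for repeated measures", {
  set.seed(22)
  n_subj <- 20
  subj <- rep(paste0("p", 1:n_subj), each = 2)
  g <- rep(c("control", "case"), times = n_subj)
  u <- rep(stats::rnorm(n_subj, 0, 0.3), each = 2)
  m <- matrix(stats::rlnorm(2 * n_subj * 2, 2 + u, 0.3), ncol = 2,
    dimnames = list(paste0("s", seq_along(subj)), c("f1", "f2"))
  )
  t <- feature_table(m)
  meta <- tibble::tibble(
    sample_id = rownames(m),
    exposure = factor(g, c("control", "case")), subject = subj
  )
  eff <- fit_study_model(t, meta, "exposure", random_group = "subject")
  expect_true(all(eff$model == "lmm"))
  expect_true(all(eff$status == "ok"))
  expect_true(all(eff$se > 0))
})

test_that("fixed-effect pooling equals the inverse-variance closed form", {
  eff <- tibble::tibble(
    study = c("a", "b", "c"),
    effect = c(0.1, 0.2, 0.3), se = c(0.05, 0.05, 0.05)
  )
  fx <- pool_effects(eff, method = "fixed")
  w <- 1 / eff$se^2
  expect_equal(fx$beta, sum(w * eff$effect) / sum(w), tolerance = 1e-12)
  expect_equal(fx$beta, 0.2, tolerance = 1e-12)
  expect_equal(fx$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(fx$tau2, 0)
  expect_equal(sum(fx$weights[[1]]), 1, tolerance = 1e-6)

  set.seed(23)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    e2 <- random_meta(k = k, tau2 = 0, seed = 100 + i)
    fx2 <- pool_effects(e2, method = "fixed")
    w2 <- 1 / e2$se^2
    expect_equal(fx2$beta, sum(w2 * e2$effect) / sum(w2), tolerance = 1e-12)
  }
})

test_that("REML tau2 matches an independent likelihood grid search", {
  # the stated three-study case has genuine heterogeneity
  eff <- tibble::tibble(
    study = c("a", "b", "c"),
    effect = c(0.1, 0.2, 0.3), se = c(0.05, 0.05, 0.05)
  )
  re <- pool_effects(eff, method = "random")
  expect_gt(re$tau2, 0)
  expect_lt(abs(re$tau2 - grid_reml_tau2(eff$effect, eff$se^2)), 1e-4)

  for (i in 1:12) {
    e2 <- random_meta(k = sample(3:8, 1), tau2 = stats::runif(1, 0, 0.1), seed = 200 + i)
    re2 <- pool_effects(e2, method = "random")
    expect_lt(abs(re2$tau2 - grid_reml_tau2(e2$effect, e2$se^2)), 1e-4)
  }

  # degenerate cases
  single <- pool_effects(eff[1, ], method = "random")
  expect_equal(single$beta, 0.1)
  expect_equal(single$tau2, 0)
  expect_equal(single$k, 1L)
  same <- pool_effects(tibble::tibble(
    study = c("a", "b"),
    effect = c(0.2, 0.2), se = c(0.1, 0.1)
  ))
  expect_equal(same$beta, 0.2, tolerance = 1e-10)
  expect_equal(same$tau2, 0, tolerance = 1e-10)
  none <- pool_effects(tibble::tibble(study = "a", effect = NA_real_, se = NA_real_))
  expect_equal(none$k, 0L)
  expect_true(is.na(none$beta))
})

test_that("Benjamini-Hochberg matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order invariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("moderator models recover interaction effects", {
  eff <- tibble::tibble(
    stratum = rep(c("sA", "sB"), each = 2),
    feature_id = rep(c("f1", "f2"), 2),
    effect = c(0.1, 0.0, 0.4, 0.2),
    se = rep(0.05, 4)
  )
  mod <- c(sA = 0, sB = 1)
  res <- moderator_test(eff, mod)
  # two strata, one per level: saturated, beta1 = b_B - b_A exactly
  expect_equal(res$beta1[res$feature_id == "f1"], 0.3, tolerance = 1e-8)
  expect_equal(res$beta1[res$feature_id == "f2"], 0.2, tolerance = 1e-8)
  expect_equal(res$beta0[res$feature_id == "f1"], 0.1, tolerance = 1e-8)

  expect_error(moderator_test(eff, c(sA = 1, sB = 1)), "constant")

  # simulated strata with an injected interaction are recovered within 2 SE
  set.seed(24)
  hits <- 0L
  for (r in 1:20) {
    k <- 6
    modr <- stats::setNames(rep(c(0, 1), each = k / 2), paste0("s", 1:k))
    d <- tibble::tibble(
      stratum = paste0("s", 1:k), feature_id = "f",
      se = stats::runif(k, 0.04, 0.08)
    )
    d$effect <- 0.05 + 0.1 * modr[d$stratum] + stats::rnorm(k, 0, d$se)
    rr <- moderator_test(d, modr)
    if (abs(rr$beta1 - 0.1) <= 2 * rr$se1) hits <- hits + 1L
  }
  expect_gte(hits, 17L) # ~95% nominal coverage over 20 replicates
})

test_that("ordinal severity contrasts behave on null and monotone data", {
  set.seed(25)
  n <- 240
  lev <- sample(c("L1", "L2", "L3"), n, replace = TRUE)
  study <- rep(c("s1", "s2"), each = n / 2)
  base <- matrix(stats::rlnorm(n * 4, 3, 0.4), n, 4,
    dimnames = list(paste0("x", 1:n), paste0("f", 1:4))
  )
  # f1 carries a monotone trend 0, d, 2d on the log scale; keep it a minor
  # community member so compositional spillover onto the others stays small
  d0 <- 0.8
  base[, 1] <- stats::rlnorm(n, 0.5, 0.4) * exp(d0 * (as.integer(factor(lev)) - 1))
  t <- feature_table(base)
  meta <- tibble::tibble(
    sample_id = rownames(base),
    severity = factor(lev, c("L1", "L2", "L3")), study = study
  )
  res <- contrast_models(t, meta, "severity")
  expect_setequal(unique(res$contrast), c("L2_vs_L1", "L3_vs_L1", "L3_incremental"))
  r1 <- res[res$feature_id == "f1", ]
  b21 <- r1$beta[r1$contrast == "L2_vs_L1"]
  b31 <- r1$beta[r1$contrast == "L3_vs_L1"]
  expect_gt(b21, 0)
  expect_gt(b31, b21)
  # unspiked features only feel the compositional spillover of f1's trend:
  # their effects stay far smaller than the spiked feature's
  rn <- res[res$feature_id != "f1" & res$contrast != "L3_incremental", ]
  expect_lt(max(abs(rn$beta)), 0.3 * b31)
  # the incremental-effect FDR pool only contains pairwise-significant features
  ri <- res[res$contrast == "L3_incremental", ]
  sig_pair <- vapply(ri$feature_id, function(f) {
    any(res$q[res$feature_id == f & res$contrast != "L3_incremental"] <= 0.05, na.rm = TRUE)
  }, logical(1))
  expect_true(all(is.na(ri$q[!sig_pair])))
  expect_true(all(!is.na(ri$q[sig_pair])))
})

test_that("the full meta-analysis pipeline pools and adjusts sensibly", {
  set.seed(26)
  n <- 60
  g <- rep(c("control", "case"), n / 2)
  m <- matrix(stats::rlnorm(n * 5, 2, 0.4), n, 5,
    dimnames = list(paste0("s", 1:n), paste0("f", 1:5))
  )
  # duplicate the same study twice
  m2 <- rbind(m, m)
  rownames(m2) <- paste0("s", seq_len(2 * n))
  t2 <- feature_table(m2)
  meta2 <- tibble::tibble(
    sample_id = rownames(m2),
    exposure = factor(rep(g, 2), c("control", "case")),
    study = rep(c("A", "B"), each = n)
  )
  res <- run_meta_da(t2, meta2, "exposure", study = "study")
  one <- fit_study_model(
    feature_table(m), tibble::tibble(
      sample_id = rownames(m),
      exposure = factor(g, c("control", "case"))
    ),
    "exposure"
  )
  expect_equal(res$pooled$beta, one$effect, tolerance = 1e-6)
  expect_true(all(res$pooled$se < one$se))
  expect_true(all(res$pooled$q >= res$pooled$p, na.rm = TRUE))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_units, 2)
  expect_s3_class(autoplot(res), "ggplot")
})
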