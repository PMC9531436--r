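# Small in-code fixtures shared across test files.

# a tiny deterministic count table
tiny_table <- function() {
  feature_table(data.frame(
    sample_id = c("s1", "s2", "s3"),
    taxA = c(2, 0, 5),
    taxB = c(2, 3, 0),
    taxC = c(0, 1, 5)
  ))
}

# two well-separated blobs in feature space, as a count table
blob_table <- function(n_per = 20, n_features = 10, sep = 50, seed = 42,
                       n_blobs = 2) {
  set.seed(seed)
  centers <- matrix(stats::runif(n_blobs * n_features, 10, 20), n_blobs)
  centers <- centers + sep * diag(nrow = n_blobs, ncol = n_features)
  m <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
    sweep(
      matrix(abs(stats::rnorm(n_per * n_features, sd = 1)), n_per),
      2L, centers[b, ], "+"
    )
  }))
  dimnames(m) <- list(
    sprintf("s%03d", seq_len(nrow(m))),
    sprintf("f%02d", seq_len(n_features))
  )
  list(
    table = feature_table(m),
    labels = rep(seq_len(n_blobs), each = n_per)
  )
}

# random meta-analysis inputs: k studies with true heterogeneity tau2
random_meta <- function(k = 5, tau2 = 0.04, seed = 1) {
  set.seed(seed)
  se <- stats::runif(k, 0.05, 0.3)
  tibble::tibble(
    study = paste0("study", seq_len(k)),
    effect = 0.2 + stats::rnorm(k, 0, sqrt(tau2)) + stats::rnorm(k, 0, se),
    se = se
  )
}

# restricted (REML) log-likelihood of a random-effects meta-analysis,
# written independently of any fitting library
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

# brute-force grid search for the REML tau2 (step-refined pure grid)
grid_reml_tau2 <- function(y, v, upper = 2) {
  lo <- 0
  hi <- upper
  for (step in c(1e-2, 1e-4, 1e-6)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, reml_loglik, numeric(1), y = y, v = v)
    best <- grid[which.max(ll)]
    lo <- max(0, best - 2 * step)
    hi <- best + 2 * step
  }
  best
}

# naive double-loop Bray-Curtis oracle
naive_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      d[a, b] <- 1 - 2 * sum(pmin(m[a, ], m[b, ])) / sum(m[a, ] + m[b, ])
    }
  }
  d
}

# one-factor PERMANOVA R2 oracle from within/total sums of squared distances
oracle_r2_factor <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  sst <- sum(d[upper.tri(d)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  1 - ssw / sst
}
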