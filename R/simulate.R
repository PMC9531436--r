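#' Zero-inflated log-normal null model
#'
#' Microbial feature abundances under the null (no metadata associations) are
#' modelled feature-wise as `LogNormal(mu_p, sigma_p^2) * Bernoulli(pi_p)`:
#' a log-normal abundance for present features, zero-inflated by a
#' per-feature presence probability. [fit_null_model()] estimates the
#' parameters from a count table; [default_null_params()] ships a fixed
#' synthetic parameter set mimicking a stool-like community (a few dominant
#' taxa, a long zero-inflated tail) for simulation when no training table is
#' at hand.
#'
#' @param t A count [feature_table()].
#' @param sigma_floor Lower bound for the log-scale standard deviation,
#'   applied when a feature has fewer than two non-zero observations or zero
#'   spread (default `1e-8`... see Details).
#' @return A tibble with columns `feature_id`, `mu` (log-mean of non-zero
#'   values), `sigma` (log-SD), `pi` (presence probability).
#' @details `pi_p` is the observed non-zero fraction; `mu_p` and `sigma_p`
#'   are the mean and standard deviation of `log` abundance over non-zero
#'   entries only.
#' @export
fit_null_model <- function(t, sigma_floor = 1e-8) {
  m <- ft_values(t)
  res <- purrr::map_dfr(seq_len(ncol(m)), function(p) {
    y <- m[, p]
    nz <- y[y > 0]
    if (length(nz) < 2L) {
      warning("feature ", colnames(m)[p], " has < 2 non-zero entries; sigma floored",
        call. = FALSE
      )
      s <- sigma_floor
    } else {
      s <- max(stats::sd(log(nz)), sigma_floor)
    }
    tibble::tibble(
      feature_id = colnames(m)[p],
      mu = if (length(nz)) mean(log(nz)) else 0,
      sigma = s,
      pi = length(nz) / length(y)
    )
  })
  res
}

#' @rdname fit_null_model
#' @param n_features Number of features to parameterize.
#' @export
default_null_params <- function(n_features) {
  # fixed internal stream: the default parameter set is a constant of the
  # package, not of the user's simulation seed
  state <- local_seed(796201L)
  on.exit(restore_seed(state), add = TRUE)
  tibble::tibble(
    feature_id = sprintf("f%04d", seq_len(n_features)),
    mu = stats::rnorm(n_features, mean = 4, sd = 2),
    sigma = stats::runif(n_features, 0.5, 2),
    pi = pmin(pmax(stats::rbeta(n_features, 0.8, 1.2), 0.05), 1)
  )
}

#' Draw a null community table
#'
#' @param params Parameter tibble as from [fit_null_model()].
#' @param n_samples Number of samples to draw.
#' @param seed Optional integer seed (draws are reproducible given it).
#' @return A count [feature_table()].
#' @export
sample_null <- function(params, n_samples, seed = NULL) {
  if (!is.null(seed)) {
    state <- local_seed(seed)
    on.exit(restore_seed(state), add = TRUE)
  }
  p <- nrow(params)
  m <- matrix(0, n_samples, p, dimnames = list(
    sprintf("s%04d", seq_len(n_samples)), params$feature_id
  ))
  for (j in seq_len(p)) {
    pres <- stats::rbinom(n_samples, 1L, params$pi[j])
    m[, j] <- pres * stats::rlnorm(n_samples, params$mu[j], params$sigma[j])
  }
  feature_table(m)
}

#' Spike a metadata association into simulated abundances
#'
#' Injects an association between a metadata variable `x` and the target
#' features by the moment-preserving re-standardization
#' `Y' = (Y + phi * ((x - mean(x)) * sd(Y) / sd(x) + mean(Y))) / (1 + phi)`,
#' applied per target feature with that feature's pre-spike sample moments.
#' The spiked feature keeps (up to truncation) its pre-spike mean and
#' approximately its variance; only the association with `x` is added.
#' Negative post-spike values are truncated to zero and the truncated
#' fraction is recorded in the `"truncated_fraction"` attribute.
#'
#' @param t A [feature_table()] (pre-spike draw).
#' @param x Numeric metadata vector, one value per sample, non-constant.
#' @param targets Feature indices or names to spike.
#' @param phi Spike strength, `>= 0`; `phi = 0` is the identity.
#' @param nonzero_only If `TRUE`, zero entries of targeted features are left
#'   at zero (presence/absence untouched); default `FALSE` applies the
#'   formula as written, so spiking may create presence.
#' @return The spiked `feature_tbl`.
#' @export
spike_in <- function(t, x, targets, phi, nonzero_only = FALSE) {
  stopifnot(phi >= 0)
  m <- ft_values(t)
  x <- as.numeric(x)
  stopifnot(length(x) == nrow(m))
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) stop("spike variable is constant", call. = FALSE)
  if (is.character(targets)) targets <- match(targets, colnames(m))
  stopifnot(all(targets >= 1L & targets <= ncol(m)))
  n_trunc <- 0L
  for (j in targets) {
    y <- m[, j]
    mu_y <- mean(y)
    s_y <- stats::sd(y)
    new <- (y + phi * ((x - mean(x)) * s_y / sx + mu_y)) / (1 + phi)
    if (nonzero_only) new[y == 0] <- 0
    n_trunc <- n_trunc + sum(new < 0)
    new[new < 0] <- 0
    m[, j] <- new
  }
  out <- feature_table(m)
  attr(out, "truncated_fraction") <- n_trunc / (length(targets) * nrow(m))
  out
}

#' Assemble a simulation scenario
#'
#' Builds the synthetic-data designs used to validate every component of the
#' package: a null community draw plus metadata spike-ins.
#'
#' * `"batch_covariate"`: batch plus a binary positive control, a continuous
#'   positive control, and a binary negative control; batch and both positive
#'   controls are spiked (the negative control never is).
#' * `"confounded_null"`: batch-spiked null data with a binary exposure whose
#'   case fraction differs across batches by `imbalance` (per-batch case
#'   fraction `0.5 +/- imbalance / 2`), but which has no effect on any
#'   feature — the design under which naive pooled tests inflate false
#'   positives.
#' * `"discrete_clusters"`: batch plus a discrete cluster label (uniform over
#'   `n_clusters`, independent of batch), both spiked.
#' * `"continuous_gradient"`: batch plus a continuous gradient
#'   `Uniform(-1, 1)`, both spiked.
#'
#' Categorical variables (batch, cluster) are spiked as level indicators:
#' each targeted feature is associated with one level's indicator, levels
#' being assigned to targets in rotation, at strength `phi`. Each variable
#' spikes its own independently drawn target set of `round(pct_spiked *
#' n_features)` features; when target sets overlap, spikes apply
#' sequentially, each using the running table's moments.
#'
#' @param kind One of `"batch_covariate"`, `"confounded_null"`,
#'   `"discrete_clusters"`, `"continuous_gradient"`.
#' @param n_batches,samples_per_batch,n_features Scenario dimensions.
#' @param pct_spiked Fraction of features associated with each spiked
#'   variable (default `0.1`).
#' @param effect_batch Spike strength for the batch variable (default `10`).
#' @param effect_covariate Spike strength for positive-control / cluster /
#'   gradient variables (default `10`).
#' @param effect_continuous Spike strength for the continuous positive
#'   control of the `"batch_covariate"` design (defaults to
#'   `effect_covariate`; set `0` for designs with a binary exposure only).
#' @param n_clusters Number of true clusters (`"discrete_clusters"` only).
#' @param imbalance Between-batch case-fraction difference of the exposure
#'   (`"confounded_null"` only; default `0.8`).
#' @param null_params Optional null-model tibble; defaults to
#'   [default_null_params()] at `n_features`.
#' @param seed Integer seed; the scenario is a pure function of its
#'   parameters and this seed.
#' @return A list of class `sim_scenario` with elements `table` (count
#'   `feature_tbl`), `metadata` (tibble with `sample_id`, `batch`, and the
#'   design's variables), and `truth` (spiked target indices per variable,
#'   effect sizes, and the latent cluster labels / gradient where relevant).
#' @export
make_scenario <- function(kind = c(
                            "batch_covariate", "confounded_null",
                            "discrete_clusters", "continuous_gradient"
                          ),
                          n_batches = 2, samples_per_batch = 100,
                          n_features = 200, pct_spiked = 0.1,
                          effect_batch = 10, effect_covariate = 10,
                          effect_continuous = effect_covariate,
                          n_clusters = 3, imbalance = 0.8,
                          null_params = NULL, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(pct_spiked >= 0, pct_spiked <= 1)
  n <- n_batches * samples_per_batch
  if (kind == "discrete_clusters" && n_clusters > n) stop("more clusters than samples", call. = FALSE)
  if (is.null(null_params)) null_params <- default_null_params(n_features)
  stopifnot(nrow(null_params) == n_features)
  state <- local_seed(seed)
  on.exit(restore_seed(state), add = TRUE)

  tab <- sample_null(null_params, n)
  batch <- factor(rep(sprintf("b%d", seq_len(n_batches)), each = samples_per_batch))
  meta <- tibble::tibble(sample_id = tab$sample_id, batch = batch)
  n_spike <- round(pct_spiked * n_features)
  truth <- list(kind = kind, seed = seed, effects = c(
    batch = effect_batch,
    covariate = effect_covariate
  ), spiked = list())

  spike_categorical <- function(tab, f, phi) {
    targets <- sample.int(n_features, n_spike)
    lev <- levels(f)
    assigned <- rep_len(sample(lev), length(targets))
    if (phi > 0) {
      for (l in unique(assigned)) {
        tab <- spike_in(tab, as.numeric(f == l), targets[assigned == l], phi)
      }
    }
    list(tab = tab, targets = targets, levels = assigned)
  }
  spike_numeric <- function(tab, x, phi) {
    targets <- sample.int(n_features, n_spike)
    if (phi > 0) tab <- spike_in(tab, x, targets, phi)
    list(tab = tab, targets = targets)
  }

  # targets are drawn even at phi = 0 so scenarios differing only in effect
  # size share their spike layout under a common seed
  sb <- spike_categorical(tab, batch, effect_batch)
  tab <- sb$tab
  truth$spiked$batch <- sb$targets

  if (kind == "batch_covariate") {
    meta$pos_binary <- factor(ifelse(stats::rbinom(n, 1, 0.5) == 1, "case", "control"),
      levels = c("control", "case")
    )
    meta$pos_continuous <- stats::rnorm(n)
    meta$neg_binary <- factor(ifelse(stats::rbinom(n, 1, 0.5) == 1, "yes", "no"),
      levels = c("no", "yes")
    )
    s1 <- spike_numeric(tab, as.numeric(meta$pos_binary == "case"), effect_covariate)
    tab <- s1$tab
    truth$spiked$pos_binary <- s1$targets
    s2 <- spike_numeric(tab, meta$pos_continuous, effect_continuous)
    tab <- s2$tab
    truth$spiked$pos_continuous <- s2$targets
  } else if (kind == "confounded_null") {
    frac <- 0.5 + imbalance / 2 * rep_len(c(1, -1), n_batches)
    pr <- frac[as.integer(batch)]
    meta$exposure <- factor(ifelse(stats::rbinom(n, 1, pr) == 1, "case", "control"),
      levels = c("control", "case")
    )
    truth$imbalance <- imbalance
  } else if (kind == "discrete_clusters") {
    cl <- factor(sprintf("c%d", sample.int(n_clusters, n, replace = TRUE)))
    meta$cluster <- cl
    sc <- spike_categorical(tab, cl, effect_covariate)
    tab <- sc$tab
    truth$spiked$cluster <- sc$targets
    truth$cluster <- cl
    truth$n_clusters <- n_clusters
  } else if (kind == "continuous_gradient") {
    grad <- stats::runif(n, -1, 1)
    meta$gradient <- grad
    sg <- spike_numeric(tab, grad, effect_covariate)
    tab <- sg$tab
    truth$spiked$gradient <- sg$targets
    truth$gradient <- grad
  }

  structure(list(table = tab, metadata = meta, truth = truth),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(
    "# Simulation scenario '", x$truth$kind, "': ",
    nrow(x$table), " samples x ", ncol(x$table) - 1L, " features, ",
    nlevels(x$metadata$batch), " batches\n",
    sep = ""
  )
  invisible(x)
}

# Seed hygiene: set the RNG locally (pinning the generator kind so results
# do not depend on the session's RNG configuration), restoring the caller's
# stream afterwards.
local_seed <- function(seed) {
  state <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed),
    kind = "Mersenne-Twister", normal.kind = "Inversion",
    sample.kind = "Rejection"
  )
  state
}

restore_seed <- function(state) {
  if (is.null(state)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible()
}
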