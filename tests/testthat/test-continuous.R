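test_that("PCA loadings are orthonormal and align with a planted factor", {
  set.seed(31)
  n <- 60
  P <- 30
  grad <- stats::runif(n, -1, 1)
  dir <- stats::rnorm(P)
  dir <- dir / sqrt(sum(dir^2))
  x <- outer(grad, dir) + matrix(stats::rnorm(n * P, 0, 0.01), n, P)
  dimnames(x) <- list(paste0("s", 1:n), paste0("f", 1:P))
  pl <- pca_top_loadings(x, threshold_v = 0.8)
  expect_gt(abs(cosine_similarity(pl$loadings[, 1], dir)), 0.99)
  expect_equal(crossprod(pl$loadings),
    diag(ncol(pl$loadings)),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  expect_equal(pl$n_kept, 1L) # one factor explains ~everything

  # threshold_v = 1 keeps the full rank of the centered matrix
  set.seed(32)
  r <- matrix(stats::rnorm(8 * 5), 8, 5, dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  pl2 <- pca_top_loadings(r, threshold_v = 1)
  expect_equal(pl2$n_kept, qr(scale(r, scale = FALSE))$rank)

  expect_error(pca_top_loadings(matrix(1, 5, 3,
    dimnames = list(paste0("s", 1:5), paste0("f", 1:3))
  )), "constant")
})

test_that("cosine similarity covers the canonical cases", {
  u <- c(1, 2, 3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  expect_error(cosine_similarity(c(0, 0), u[1:2]), "zero-norm")
})

test_that("the PC network links twin studies and thresholds monotonically", {
  set.seed(33)
  m <- matrix(stats::rlnorm(50 * 40, 2, 1), 50, 40,
    dimnames = list(paste0("s", 1:50), paste0("f", 1:40))
  )
  t <- feature_table(m)
  pl <- pca_top_loadings(t)
  net <- build_pc_network(list(A = pl, B = pl), threshold_s = 0.7)
  # each PC pairs with its twin at weight 1
  twin <- net$edges[net$edges$weight > 1 - 1e-8, ]
  expect_equal(nrow(twin), pl$n_kept)
  expect_true(all(sub("^A\\.", "", twin$from) == sub("^B\\.", "", twin$to)))
  # no within-study edges ever
  expect_false(any(sub("\\..*$", "", net$edges$from) == sub("\\..*$", "", net$edges$to)))

  # random independent high-dimensional loadings: no edges at 0.7
  set.seed(34)
  mk <- function(seed) {
    set.seed(seed)
    x <- matrix(stats::rnorm(30 * 1000), 30, 1000,
      dimnames = list(paste0("s", 1:30), paste0("f", 1:1000))
    )
    pca_top_loadings(x, threshold_v = 0.3)
  }
  net0 <- build_pc_network(list(A = mk(1), B = mk(2)), threshold_s = 0.7)
  expect_equal(nrow(net0$edges), 0L)

  # lowering the threshold only ever adds edges
  lo <- build_pc_network(list(A = pl, B = pl), threshold_s = 0.5)
  hi <- build_pc_network(list(A = pl, B = pl), threshold_s = 0.8)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(hi$edges) %in% key(lo$edges)))
  expect_true(all(key(net$edges) %in% key(lo$edges)))
})

test_that("modularity modules find cliques and drop singletons", {
  fake_net <- function(edges, nodes) {
    structure(
      list(
        nodes = tibble::tibble(node = nodes, study = sub("\\..*", "", nodes)),
        edges = edges, threshold_s = 0.7
      ),
      class = "pc_network"
    )
  }
  ed <- tibble::tibble(
    from = c("A.PC1", "A.PC1", "B.PC1", "A.PC2", "A.PC2", "B.PC2"),
    to = c("B.PC1", "C.PC1", "C.PC1", "B.PC2", "C.PC2", "C.PC2"),
    weight = 0.9
  )
  nodes <- c(
    "A.PC1", "B.PC1", "C.PC1", "A.PC2", "B.PC2", "C.PC2",
    "A.PC3" # isolated
  )
  mods <- detect_modules(fake_net(ed, nodes))
  expect_equal(length(mods), 2L)
  found <- lapply(mods, sort)
  expect_true(list(c("A.PC1", "B.PC1", "C.PC1")) %in% found ||
    identical(found[[1]], c("A.PC1", "B.PC1", "C.PC1")) ||
    identical(found[[2]], c("A.PC1", "B.PC1", "C.PC1")))
  expect_true(identical(found[[1]], c("A.PC2", "B.PC2", "C.PC2")) ||
    identical(found[[2]], c("A.PC2", "B.PC2", "C.PC2")))
  expect_false(any(vapply(mods, function(m) "A.PC3" %in% m, logical(1))))
  expect_equal(detect_modules(fake_net(ed[0, ], nodes)), list())
})

test_that("consensus loadings sign-correct members and refuse frustration", {
  w <- c(0.6, 0.8, 0)
  net <- list(loadings = cbind(A.PC1 = w, B.PC1 = -w))
  cl <- consensus_loading(net, c("A.PC1", "B.PC1"))
  expect_equal(unname(cl$w), w)
  net2 <- list(loadings = cbind(A.PC1 = w, B.PC1 = w))
  expect_equal(unname(consensus_loading(net2, c("A.PC1", "B.PC1"))$w), w)

  # frustrated triple: +,+,- cosines cannot be sign-corrected
  a <- c(1, 0, 0)
  b <- c(0.6, 0.8, 0)
  cc <- c(0.6, -0.8, 0)
  net3 <- list(loadings = cbind(A.PC1 = a, B.PC1 = b, C.PC1 = cc))
  expect_error(
    consensus_loading(net3, c("A.PC1", "B.PC1", "C.PC1")),
    "higher threshold_s"
  )

  # unit-norm variant
  cl2 <- consensus_loading(net, c("A.PC1", "B.PC1"), unit_norm = TRUE)
  expect_equal(sum(cl2$w^2), 1)
})

test_that("scores are centered projections equal to PC scores", {
  set.seed(35)
  m <- matrix(stats::rlnorm(40 * 20, 2, 1), 40, 20,
    dimnames = list(paste0("s", 1:40), paste0("f", 1:20))
  )
  t <- feature_table(m)
  pl <- pca_top_loadings(t)
  w <- stats::setNames(pl$loadings[, 1], rownames(pl$loadings))
  sc <- assign_scores(t, w)
  x <- scale(transformed_abundance(t), center = TRUE, scale = FALSE)
  expect_equal(stats::cor(sc$score, drop(x %*% pl$loadings[, 1])), 1, tolerance = 1e-12)

  # adding a constant to one feature's transformed values leaves scores as-is
  x2 <- transformed_abundance(t)
  x2[, 3] <- x2[, 3] + 0.1
  sc2 <- assign_scores(x2, w)
  expect_equal(sc2$score, assign_scores(transformed_abundance(t), w)$score,
    tolerance = 1e-12
  )
})

test_that("consensus validation accepts the training study and rejects noise", {
  set.seed(36)
  n <- 60
  P <- 40
  grad <- stats::runif(n, -1, 1)
  dir <- stats::rnorm(P)
  dir <- dir / sqrt(sum(dir^2))
  x <- outer(grad, dir) * 0.3 + matrix(stats::rnorm(n * P, 0, 0.02), n, P)
  dimnames(x) <- list(paste0("s", 1:n), paste0("f", 1:P))
  pl <- pca_top_loadings(x)
  w <- stats::setNames(pl$loadings[, 1], rownames(pl$loadings))

  v_self <- validate_consensus(w, x)
  expect_true(v_self$validated)
  expect_gt(v_self$max_abs_cosine, 0.99)

  perm <- apply(x, 1L, sample) # destroy the structure feature-wise
  perm <- t(perm)
  dimnames(perm) <- dimnames(x)
  v_perm <- validate_consensus(w, perm)
  expect_false(v_perm$validated)
})

test_that("the full continuous pipeline recovers planted twin gradients", {
  set.seed(37)
  P <- 60
  n <- 80
  dir1 <- stats::rnorm(P)
  dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- stats::rnorm(P)
  dir2 <- dir2 - sum(dir2 * dir1) * dir1
  dir2 <- dir2 / sqrt(sum(dir2^2))
  mk <- function(seed) {
    set.seed(seed)
    g1 <- stats::runif(n, -1, 1)
    g2 <- stats::runif(n, -1, 1)
    x <- outer(g1, dir1) + 0.7 * outer(g2, dir2) +
      matrix(stats::rnorm(n * P, 0, 0.05), n, P)
    dimnames(x) <- list(paste0("s", 1:n), paste0("f", 1:P))
    x
  }
  tabs <- list(A = mk(1), B = mk(2), C = mk(3), D = mk(4))
  loading_sets <- lapply(tabs, pca_top_loadings, threshold_v = 0.6)
  net <- build_pc_network(loading_sets, threshold_s = 0.7)
  mods <- detect_modules(net)
  expect_equal(length(mods), 2L)
  expect_true(all(lengths(mods) == 4L)) # one PC per study in each module
  cl <- consensus_loading(net, mods[[1]])
  expect_gt(
    max(
      abs(cosine_similarity(cl$w, dir1)),
      abs(cosine_similarity(cl$w, dir2))
    ),
    0.98
  )
})
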