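test_that("feature tables validate their invariants", {
  t <- tiny_table()
  expect_s3_class(t, "feature_tbl")
  expect_false(is_relative(t))
  expect_error(
    feature_table(data.frame(sample_id = c("s1", "s1"), f = c(1, 2))),
    "duplicated sample_id"
  )
  expect_error(
    feature_table(data.frame(sample_id = "s1", f = -1)),
    "negative"
  )
  expect_error(
    feature_table(data.frame(sample_id = "s1", f = NA_real_)),
    "missing"
  )
  expect_error(
    feature_table(data.frame(sample_id = "s1", f = 0.5), is_relative = TRUE),
    "row sums"
  )
})

test_that("TSV round-trip preserves values in both orientations", {
  t <- tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(t, path)
  back <- read_feature_table(path)
  expect_equal(ft_values(back), ft_values(t))

  # features-in-rows orientation
  path2 <- withr::local_tempfile(fileext = ".tsv")
  m <- t(ft_values(t))
  utils::write.table(
    data.frame(feature_id = rownames(m), m, check.names = FALSE),
    path2,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  back2 <- read_feature_table(path2, orientation = "features")
  expect_equal(ft_values(back2), ft_values(t))

  # duplicated sample id is refused at parse
  writeLines(c("id\tf1", "s1\t1", "s1\t2"), path2)
  expect_error(read_feature_table(path2), "duplicated sample_id")
})

test_that("TSS normalization closes rows and is idempotent", {
  t <- feature_table(data.frame(sample_id = c("a", "b"), f1 = c(2, 5), f2 = c(2, 0), f3 = c(0, 0)))
  n1 <- tss_normalize(t)
  expect_equal(unname(ft_values(n1)[1, ]), c(0.5, 0.5, 0))
  expect_equal(unname(ft_values(n1)[2, ]), c(1, 0, 0))
  expect_true(is_relative(n1))
  expect_equal(ft_values(tss_normalize(n1)), ft_values(n1))
  t0 <- feature_table(data.frame(sample_id = "z", f1 = 0, f2 = 0))
  expect_error(tss_normalize(t0), "all-zero")
})

test_that("arcsine square-root transform matches closed forms and bounds", {
  p <- matrix(c(0, 1, 0.25, 0.5), 2, dimnames = list(c("a", "b"), c("x", "y")))
  out <- arcsin_sqrt(p)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], pi / 2)
  expect_equal(out[1, 2], pi / 6)
  expect_true(all(out >= 0 & out <= pi / 2))
  expect_error(arcsin_sqrt(matrix(1.2)), "outside")
  expect_error(arcsin_sqrt(tiny_table()), "relative")
})

test_that("quality filter applies depth, abundance and prevalence rules", {
  # depths: 2999 (removed, strict <), 3000 (kept), 5000 (kept)
  m <- rbind(
    s1 = c(f1 = 2600, f2 = 399, f3 = 0),
    s2 = c(f1 = 2000, f2 = 999, f3 = 1),
    s3 = c(f1 = 4000, f2 = 0, f3 = 1000)
  )
  t <- feature_table(m)
  out <- filter_quality(t, studies = c("A", "A", "A"), min_depth = 3000)
  expect_equal(rownames(ft_values(out)), c("s2", "s3"))
  # f3: rel abundance 1/3000 > 5e-5 in s2 and 0.2 in s3 -> prevalence 1 in study A
  expect_true("f3" %in% colnames(ft_values(out)))

  # feature present at 1e-4 in half of one study's samples passes defaults
  m2 <- cbind(
    common = rep(10000, 4),
    rare = c(1, 1, 0, 0) # 1e-4 relative, 50% prevalence
  )
  rownames(m2) <- paste0("s", 1:4)
  out2 <- filter_quality(feature_table(m2), studies = rep("A", 4), min_depth = 0)
  expect_true("rare" %in% colnames(ft_values(out2)))
  # absent everywhere is removed
  m3 <- cbind(m2, never = 0)
  out3 <- filter_quality(feature_table(m3), studies = rep("A", 4), min_depth = 0)
  expect_false("never" %in% colnames(ft_values(out3)))

  # fully permissive settings are the identity
  id <- filter_quality(tiny_table(),
    studies = c("A", "A", "B"),
    min_abund = 0, min_prev = 0, min_depth = 0
  )
  expect_equal(ft_values(id), ft_values(tiny_table()))
})

test_that("taxonomic aggregation conserves totals and pools unclassified", {
  t <- feature_table(data.frame(
    sample_id = c("s1", "s2"),
    otu1 = c(5, 1), otu2 = c(3, 2), otu3 = c(2, 8)
  ))
  tax <- data.frame(
    feature_id = c("otu1", "otu2", "otu3"),
    family = c("Enterobacteriaceae", "Enterobacteriaceae", "Lachnospiraceae"),
    genus = c("Escherichia", "Escherichia", NA)
  )
  out <- aggregate_taxonomy(t, tax, "genus")
  v <- ft_values(out)
  expect_equal(sort(colnames(v)), sort(c("Escherichia", "Lachnospiraceae unclassified")))
  expect_equal(unname(v[, "Escherichia"]), c(8, 3))
  expect_equal(unname(v[, "Lachnospiraceae unclassified"]), c(2, 8))
  expect_equal(rowSums(v), rowSums(ft_values(t)))
  expect_error(
    aggregate_taxonomy(t, tax[-1, ], "genus"),
    "missing from taxonomy"
  )
})

test_that("Bray-Curtis matches closed forms and the naive oracle", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), d = c(0, 0, 2))
  colnames(m) <- c("x", "y", "z")
  d <- bray_curtis(feature_table(m))
  expect_equal(d["a", "c"], 0) # identical rows
  expect_equal(d["a", "d"], 1) # disjoint support
  expect_equal(d["a", "b"], 0.5) # 1 - 2*1/4
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), rownames(m)))

  set.seed(7)
  for (i in 1:3) {
    r <- matrix(stats::rexp(50), 10, 5)
    r[sample(50, 10)] <- 0
    r[rowSums(r) == 0, 1] <- 1
    dimnames(r) <- list(paste0("s", 1:10), paste0("f", 1:5))
    expect_equal(unname(bray_curtis(feature_table(r))), naive_bray(r),
      tolerance = 1e-12
    )
  }
})

test_that("Jaccard and root-JSD match their naive oracles", {
  set.seed(11)
  m <- matrix(stats::rpois(40, 3), 8, 5)
  m[rowSums(m) == 0, 1] <- 1
  dimnames(m) <- list(paste0("s", 1:8), paste0("f", 1:5))
  t <- feature_table(m)

  dj <- dissimilarity(t, "jaccard")
  for (a in 1:7) {
    for (b in (a + 1):8) {
      A <- m[a, ] > 0
      B <- m[b, ] > 0
      expect_equal(dj[a, b], 1 - sum(A & B) / sum(A | B), tolerance = 1e-12)
    }
  }

  dr <- dissimilarity(t, "rjsd")
  expect_equal(diag(dr), setNames(rep(0, 8), rownames(m)))
  kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
  rel <- m / rowSums(m)
  for (a in 1:7) {
    for (b in (a + 1):8) {
      mix <- (rel[a, ] + rel[b, ]) / 2
      expect_equal(dr[a, b], sqrt((kl(rel[a, ], mix) + kl(rel[b, ], mix)) / 2),
        tolerance = 1e-12
      )
    }
  }
  # identical rows at zero
  m2 <- rbind(m[1, ], m[1, ])
  rownames(m2) <- c("u", "v")
  expect_equal(dissimilarity(feature_table(m2), "rjsd")["u", "v"], 0)
})
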