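test_that("contrast data keeps marginals but breaks dependence", {
  sim <- cached_sim(100, seed = 5)
  cd <- make_contrast_data(sim$cohort, seed = 2)
  expect_equal(nrow(cd$features), 200)
  expect_equal(as.integer(table(cd$class)), c(100, 100))

  # a constant feature stays constant in the synthetic class
  feat <- cohort_features(sim$cohort)
  feat$age <- 50
  cd2 <- make_contrast_data(feat, seed = 2)
  expect_true(all(cd2$features$age == 50))

  # strongly correlated columns decorrelate under marginal resampling
  set.seed(8)
  z <- rnorm(1e4)
  df <- data.frame(a = z, b = z + rnorm(1e4, 0, 0.05))
  cd3 <- make_contrast_data(df, seed = 3)
  synth <- cd3$features[cd3$class == "synthetic", ]
  expect_gt(cor(df$a, df$b), 0.99)
  expect_lt(abs(cor(synth$a, synth$b)), 0.05)
})

test_that("the unsupervised forest separates structured data from its marginals", {
  sim <- cached_sim(200, seed = 5)
  f <- fit_unsupervised_forest(sim$cohort, ntree = 60, seed = 4)
  expect_equal(f$rf$ntree, 60)
  expect_lt(f$oob_error, 0.5)  # dependence structure is learnable
  expect_equal(f$mtry, ncol(encode_features(sim$cohort)))  # default: all predictors

  # node assignments are deterministic functions of the features
  feat <- cohort_features(sim$cohort)
  n1 <- terminal_node_ids(f, feat[c(1, 1, 2), ])
  expect_identical(n1[1, ], n1[2, ])
  expect_equal(dim(n1), c(3L, 60L))
})

test_that("single-tree proximities are 0/1 and self-proximity equals the tree count", {
  sim <- cached_sim(100, seed = 5)
  f1 <- fit_unsupervised_forest(sim$cohort, ntree = 1, seed = 4)
  nodes <- terminal_node_ids(f1, sim$cohort)
  pr <- proximity(nodes, nodes)
  expect_true(all(pr %in% c(0L, 1L)))
  expect_true(all(diag(pr) == 1L))

  f <- fit_unsupervised_forest(sim$cohort, ntree = 25, seed = 4)
  nodes <- terminal_node_ids(f, sim$cohort)
  pr <- proximity(nodes, nodes)
  expect_true(all(diag(pr) == 25L))
  expect_identical(pr, t(pr))
  expect_true(all(pr >= 0 & pr <= 25))
})

test_that("blocked proximity equals brute-force (pair, tree) counting", {
  sim <- cached_sim(100, seed = 5)
  f <- fit_unsupervised_forest(sim$cohort, ntree = 25, seed = 4)
  feat <- cohort_features(sim$cohort)
  nodes_a <- terminal_node_ids(f, feat[1:30, ])
  nodes_b <- terminal_node_ids(f, feat[31:80, ])
  expect_identical(proximity(nodes_a, nodes_b),
                   proximity_bruteforce(nodes_a, nodes_b))
  expect_identical(proximity(nodes_a, nodes_a),
                   proximity_bruteforce(nodes_a, nodes_a))
  expect_error(proximity(nodes_a[, 1:10], nodes_b), "mismatch")
})

test_that("PSM normalization forms a probability vector with declared degenerate behavior", {
  expect_equal(normalize_psm(c(3, 1, 0)), c(0.75, 0.25, 0))
  expect_equal(normalize_psm(rep(7, 5)), rep(0.2, 5))
  expect_warning(w <- normalize_psm(c(0, 0, 0)), "uniform")
  expect_equal(w, rep(1 / 3, 3))
  # self-exclusion zeroes the index before renormalizing
  expect_equal(normalize_psm(c(10, 3, 1), exclude = 1), c(0, 0.75, 0.25))
  expect_error(normalize_psm(numeric(0)), "empty")
  expect_error(normalize_psm(c(1, -1)), "negative")

  # conservation across many random rows
  set.seed(31)
  for (i in 1:50) {
    row <- rpois(20, 3)
    if (sum(row) == 0) row[1] <- 1
    expect_lt(abs(sum(normalize_psm(row)) - 1), 1e-12)
  }
})

test_that("neighbor ranking is deterministic and denominator-invariant", {
  expect_equal(rank_similar(c(0.5, 0.2, 0.3), 2), c(1, 3))
  expect_equal(rank_similar(rep(0.25, 4), 3), c(1, 2, 3))  # ties: ascending index
  expect_equal(rank_similar(c(0.1, 0.9), 2), c(2, 1))
  expect_error(rank_similar(c(0.5, 0.5), 3), "M must be")

  # ranking identical whether counts are scaled by row sum or tree count
  set.seed(12)
  for (i in 1:20) {
    counts <- rpois(30, 4)
    counts[1] <- counts[1] + 1
    by_rowsum <- normalize_psm(counts)
    by_ntree <- normalize_psm(counts, denominator = "ntree", ntree = 50)
    expect_identical(rank_similar(by_rowsum, 10), rank_similar(by_ntree, 10))
  }
})

test_that("cosine PSM matches the direct dot-product formula", {
  sch <- feature_schema(
    data.frame(name = c("a", "b", "c"), kind = "numeric", unit = "", group = "other"))
  train <- data.frame(a = c(1, 0, 5), b = c(0, 1, 5), c = c(0, 0, 5))
  idx <- data.frame(a = 1, b = 0, c = 0)
  w <- cosine_psm(idx, train, sch)
  # oracle: z-scale by training stats, then cosine by direct formula
  mu <- colMeans(train); sdv <- apply(train, 2, sd)
  Z <- sweep(sweep(as.matrix(train), 2, mu), 2, sdv, "/")
  zi <- (as.numeric(idx) - mu) / sdv
  co <- as.numeric(Z %*% zi) / (sqrt(sum(zi^2)) * sqrt(rowSums(Z^2)))
  expect_equal(attr(w, "cosine"), co, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # an index identical to a training row gets the maximal weight
  w2 <- cosine_psm(train[2, ], train, sch)
  expect_equal(which.max(w2), 2L)
})
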