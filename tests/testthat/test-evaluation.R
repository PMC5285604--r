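test_that("fold plans partition the cohort with near-equal sizes", {
  fp <- make_folds(100, 10, seed = 1)
  expect_equal(sort(unique(fp$assignment)), 1:10)
  expect_true(all(tabulate(fp$assignment, 10) == 10))

  fp2 <- make_folds(17, 10, seed = 1)
  expect_true(all(tabulate(fp2$assignment, 10) %in% 1:2))
  expect_identical(make_folds(50, 5, seed = 3)$assignment,
                   make_folds(50, 5, seed = 3)$assignment)
  expect_error(make_folds(5, 10), "at least")

  y <- rep(c(0, 1), c(80, 20))
  fps <- make_folds(100, 10, seed = 2, stratify = y)
  expect_true(all(tabulate(fps$assignment[y == 1], 10) == 2))
})

test_that("AUROC matches hand-worked and boundary cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(1:10, rep(c(0, 1), each = 5)), 1)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), each = 5)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
})

test_that("AUROC equals pair enumeration and satisfies its invariances", {
  set.seed(55)
  for (i in 1:300) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    a <- auroc(s, y)
    expect_equal(a, auroc_pairs(s, y), tolerance = 1e-12)
    expect_equal(a + auroc(s, 1 - y), 1, tolerance = 1e-12)
    expect_equal(auroc(exp(3 * s), y), a, tolerance = 1e-12)  # monotone invariance
  }
})

test_that("AUPRC equals threshold enumeration with tie blocks", {
  set.seed(56)
  expect_equal(auprc(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0)), 1)
  expect_equal(auprc(rep(1, 10), rep(c(0, 1), each = 5)), 0.5)  # prevalence
  expect_error(auprc(1:3, rep(0, 3)), "no positives")
  for (i in 1:300) {
    n <- sample(4:20, 1)
    y <- c(1, rbinom(n - 1, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    expect_equal(auprc(s, y), auprc_thresholds(s, y), tolerance = 1e-12)
  }
  # labels as their own scores: at least the prevalence
  for (i in 1:25) {
    y <- c(1, 0, rbinom(10, 1, 0.5))
    expect_gte(auprc(y, y), mean(y))
  }
})

test_that("fold summaries use the t-based 95% interval", {
  expect_equal(unname(summarize_ci(rep(0.8, 10))), c(0.8, 0.8, 0.8))
  ci <- summarize_ci(c(0, 1))
  hw <- qt(0.975, 1) * sd(c(0, 1)) / sqrt(2)
  expect_equal(unname(ci), c(0.5, 0.5 - hw, 0.5 + hw))
  expect_error(summarize_ci(0.5), "at least 2")

  # coverage of the nominal 95% level
  set.seed(90)
  cover <- mean(replicate(1000, {
    ci <- summarize_ci(rnorm(10, 0.8, 0.01))
    ci["lower"] <= 0.8 && 0.8 <= ci["upper"]
  }))
  expect_gt(cover, 0.92); expect_lt(cover, 0.98)
})

test_that("the paired comparison behaves at its limits", {
  expect_equal(compare_best_vs_all(rep(0.8, 10), rep(0.8, 10)), 1)
  set.seed(91)
  jit <- rnorm(10, 0, 1e-6)
  expect_lt(compare_best_vs_all(rep(0.9, 10) + jit, rep(0.8, 10)), 0.001)
  # zero-variance nonzero differences: exact sign test
  expect_equal(compare_best_vs_all(rep(0.9, 4), rep(0.8, 4)),
               binom.test(4, 4)$p.value)
})

test_that("sweep bookkeeping: one record per (family, M, fold) plus the all-data row", {
  sim <- cached_sim(200, seed = 19)
  grid <- c(20, 60, 120)
  sw <- run_sweep(sim$cohort, families = "dc", grids = list(dc = grid),
                  k = 4, seed = 3, psm_control = list(ntree = 25))
  rec <- sw$records
  expect_equal(nrow(rec), (length(grid) + 1) * 4)
  expect_equal(sum(rec$condition == "all_data"), 4)
  expect_true(all(rec$auroc >= 0 & rec$auroc <= 1))
  expect_true(all(rec$auprc >= 0 & rec$auprc <= 1))
  expect_equal(nrow(unique(rec[, c("family", "M", "fold")])), nrow(rec))
  # all-data death counting scores everyone at the training rate: chance AUROC
  expect_true(all(rec$auroc[rec$condition == "all_data"] == 0.5))

  expect_error(run_sweep(sim$cohort, families = "dc",
                         grids = list(dc = c(10, 5000)), k = 4, seed = 3),
               "infeasible")
})

test_that("fitted families and CSRF run through the sweep on a small cohort", {
  sim <- cached_sim(200, seed = 19)
  sw <- run_sweep(sim$cohort, families = c("lr", "dt", "rf", "csrf"),
                  grids = list(lr = c(50, 120), dt = c(50, 120),
                               rf = c(50, 120)),
                  k = 3, seed = 5, psm_control = list(ntree = 25),
                  model_control = list(rf_ntree = 25, csrf_ntree = 25),
                  test_subsample = 20)
  rec <- sw$records
  # grid families: (2 M + all-data) x 3 folds; CSRF: one condition x 3 folds
  for (f in c("lr", "dt", "rf"))
    expect_equal(sum(rec$family == f), 9)
  expect_equal(sum(rec$family == "csrf"), 3)
  expect_true(all(is.na(rec$M[rec$family == "csrf"])))
  expect_true(all(rec$auroc >= 0 & rec$auroc <= 1))
})

test_that("sweeps are reproducible under a fixed seed", {
  sim <- cached_sim(200, seed = 19)
  run <- function() run_sweep(sim$cohort, families = "dc",
                              grids = list(dc = c(20, 80)), k = 3, seed = 8,
                              psm_control = list(ntree = 20))
  expect_identical(run()$records, run()$records)
})
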