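test_that("death counting is exactly the neighborhood death fraction", {
  expect_equal(train_death_counting(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))$constant_risk, 0.3)
  expect_equal(train_death_counting(rep(0, 5))$constant_risk, 0)
  m <- train_death_counting(c(1, 0, 0, 0))
  sim <- cached_sim(40, seed = 7)
  expect_equal(predict_risk(m, cohort_features(sim$cohort)[1:3, ]),
               rep(0.25, 3))
  expect_error(train_death_counting(integer(0)), "empty")
  expect_error(train_death_counting(c(0, 2)), "0/1")

  # monotone in composition: adding a death never lowers the risk
  set.seed(4)
  for (i in 1:25) {
    y <- rbinom(sample(2:30, 1), 1, 0.3)
    expect_gte(train_death_counting(c(y, 1))$constant_risk,
               train_death_counting(y)$constant_risk)
  }
})

test_that("degenerate predictors are dropped before local fitting", {
  sim <- cached_sim(60, seed = 7)
  sch <- cohort_schema(sim$cohort)
  feat <- cohort_features(sim$cohort)
  feat$gender <- factor("male", levels = c("female", "male"))  # all-male
  dd <- drop_degenerate_predictors(feat, sch)
  expect_true("gender" %in% dd$dropped)
  expect_false("gender" %in% dd$schema$entries$name)

  # identity when nothing is constant
  dd2 <- drop_degenerate_predictors(cohort_features(sim$cohort), sch)
  expect_length(dd2$dropped, 0)
  expect_equal(n_predictors(dd2$schema), 75)

  # everything constant: downstream falls back to the neighborhood rate
  const <- feat[rep(1, 10), ]
  dd3 <- drop_degenerate_predictors(const, sch)
  expect_length(dd3$dropped, 75)
  m <- train_local_model("LR", const, c(1, 1, rep(0, 8)), sch)
  expect_equal(m$constant_risk, 0.2)
})

test_that("single-class neighborhoods yield constant risk without fitting", {
  sim <- cached_sim(60, seed = 7)
  feat <- cohort_features(sim$cohort)
  for (fam in c("LR", "DT", "RF")) {
    m <- train_local_model(fam, feat[1:20, ], rep(0, 20),
                           cohort_schema(sim$cohort))
    expect_equal(predict_risk(m, feat[21, ]), 0)
    m1 <- train_local_model(fam, feat[1:20, ], rep(1, 20),
                            cohort_schema(sim$cohort))
    expect_equal(predict_risk(m1, feat[21, ]), 1)
  }
})

test_that("logistic regression recovers known generating coefficients", {
  sch <- feature_schema(
    data.frame(name = c("x1", "x2", "x3"), kind = "numeric",
               unit = "", group = "other"))
  set.seed(77)
  n <- 4000
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  beta <- c(0.8, -0.5, 0.3); a <- -1.2
  y <- rbinom(n, 1, plogis(a + as.matrix(X) %*% beta))
  m <- train_local_model("LR", X, y, sch)
  expect_equal(m$family, "LR")
  est <- coef(m$fit)
  se <- sqrt(diag(vcov(m$fit)))
  expect_true(all(abs(est - c(a, beta)) < 3 * se))

  # prediction at the fitted linear predictor's zero point is 0.5
  zero_pt <- data.frame(x1 = 0, x2 = 0, x3 = 0)
  # solve for x1 holding others at 0: a + b1*x1 = 0
  zero_pt$x1 <- -est[1] / est[2]
  expect_equal(predict_risk(m, zero_pt), 0.5, tolerance = 1e-8)
})

test_that("logistic regression falls back to constant risk under separation", {
  sch <- feature_schema(
    data.frame(name = "x1", kind = "numeric", unit = "", group = "other"))
  X <- data.frame(x1 = c(-(5:1), 1:5))
  y <- c(rep(0, 5), rep(1, 5))  # perfectly separated
  m <- train_local_model("LR", X, y, sch)
  expect_equal(m$constant_risk, 0.5)
  expect_match(m$note, "separation")
})

test_that("a decision tree reproduces labels on separable one-feature data", {
  sch <- feature_schema(
    data.frame(name = "x1", kind = "numeric", unit = "", group = "other"))
  X <- data.frame(x1 = c(rep(0, 25), rep(10, 25)))
  y <- c(rep(0, 25), rep(1, 25))
  m <- train_local_model("DT", X, y, sch)
  expect_equal(predict_risk(m, X), y)
})

test_that("all families emit probabilities in [0, 1], deterministically under a seed", {
  sim <- cached_sim(200, seed = 19)
  feat <- cohort_features(sim$cohort)
  y <- sim$cohort$death_30d
  sch <- cohort_schema(sim$cohort)
  idx <- feat[181:200, ]
  for (fam in c("LR", "DT", "RF")) {
    m1 <- train_local_model(fam, feat[1:180, ], y[1:180], sch,
                            seed = 5, ntree = 50)
    p1 <- predict_risk(m1, idx)
    expect_true(all(p1 >= 0 & p1 <= 1))
    m2 <- train_local_model(fam, feat[1:180, ], y[1:180], sch,
                            seed = 5, ntree = 50)
    expect_identical(p1, predict_risk(m2, idx))
  }
})

test_that("RF risk is the fraction of trees voting death", {
  sim <- cached_sim(200, seed = 19)
  feat <- cohort_features(sim$cohort)
  y <- sim$cohort$death_30d
  m <- train_local_model("RF", feat[1:150, ], y[1:150],
                         cohort_schema(sim$cohort), seed = 2, ntree = 40)
  p <- predict_risk(m, feat[151:160, ])
  votes <- p * 40
  expect_equal(votes, round(votes), tolerance = 1e-9)
})
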