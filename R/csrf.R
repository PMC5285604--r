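#' Configuration for the case-specific random forest
#'
#' Defaults follow the case-specific-forest convention: 500 trees, minimum
#' terminal node size 1, and `mtry = floor(sqrt(p))` over the encoded
#' predictors.
#'
#' @param ntree number of trees (default 500).
#' @param nodesize minimum terminal node size (default 1).
#' @param mtry candidate predictors per split; `NULL` means
#'   `floor(sqrt(p))` at fit time.
#' @param seed integer seed; each tree uses an RNG stream derived from
#'   `(seed, tree index)`.
#' @return A `csrf_config` list.
#' @export
csrf_config <- function(ntree = 500, nodesize = 1, mtry = NULL, seed = 1L) {
  stopifnot(ntree >= 1, nodesize >= 1)
  structure(list(ntree = as.integer(ntree), nodesize = as.integer(nodesize),
                 mtry = mtry, seed = as.integer(seed)),
            class = "csrf_config")
}

#' Weighted bootstrap draw
#'
#' Draws `n_draw` training indices independently with replacement, each
#' index j selected with probability `weights[j]`. This is the sampling
#' primitive of the case-specific random forest, where the similarity
#' weights of the index patient replace the uniform bootstrap.
#'
#' @param weights nonnegative weights summing to 1.
#' @param n_draw number of draws.
#' @param seed optional integer seed.
#' @return Integer vector of length `n_draw` (a multiset of indices).
#' @export
weighted_bootstrap <- function(weights, n_draw, seed = NULL) {
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and nonnegative")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  sample.int(length(weights), n_draw, replace = TRUE, prob = weights)
}

#' Fit a case-specific random forest for one index patient
#'
#' Grows `ntree` trees; each tree's bootstrap sample of size `n_train` is
#' drawn with probabilities proportional to the index patient's similarity
#' weights over the whole training set (soft thresholding - no neighborhood
#' cutoff). With uniform weights the procedure is exactly a standard random
#' forest grown through the same sampling machinery, which makes the
#' uniform-weight case a strict equivalence check. Trees whose weighted
#' sample is single-class cast a constant vote; prediction is the fraction
#' of trees voting death.
#'
#' @param train a `cohort_table` of training patients.
#' @param weights similarity weights over the training rows (sum 1); `NULL`
#'   gives the uniform bootstrap (standard random forest).
#' @param config a [csrf_config()].
#' @return A `risk_model` of family `"CSRF"`.
#' @export
fit_csrf <- function(train, weights = NULL, config = csrf_config()) {
  stopifnot(inherits(train, "cohort_table"), inherits(config, "csrf_config"))
  n <- nrow(train)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("weights not aligned with training rows")
  schema <- cohort_schema(train)
  X <- encode_features(train)
  y <- train$death_30d
  p <- ncol(X)
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(p))) else min(config$mtry, p)

  trees <- vector("list", config$ntree)
  for (t in seq_len(config$ntree)) {
    idx <- weighted_bootstrap(weights, n, seed = config$seed + t)
    yb <- y[idx]
    if (length(unique(yb)) < 2) {
      trees[[t]] <- list(constant = yb[1])
      next
    }
    trees[[t]] <- randomForest::randomForest(
      x = X[idx, , drop = FALSE],
      y = factor(yb, levels = c(0, 1)),
      ntree = 1, mtry = mtry, nodesize = config$nodesize,
      replace = FALSE, sampsize = length(idx))
  }
  model <- new_risk_model("CSRF", fit = list(trees = trees, config = config),
                          sub_schema = schema, encoded_cols = colnames(X))
  model
}

predict_csrf_votes <- function(model, X) {
  trees <- model$fit$trees
  votes <- matrix(0, nrow(X), length(trees))
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    votes[, t] <- if (!is.null(tr$constant)) tr$constant
    else as.numeric(as.character(stats::predict(tr, newdata = X,
                                                type = "response")))
  }
  rowMeans(votes)
}
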