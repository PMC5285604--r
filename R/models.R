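#' @title Personalized risk models over a similarity neighborhood
#' @description For each index patient, a model is trained on the M most
#'   similar training patients only. Four families are supported: death
#'   counting (DC; the neighborhood death fraction as a constant risk),
#'   logistic regression (LR; `stats::glm` defaults), decision tree (DT;
#'   `rpart` defaults) and random forest (RF; `randomForest` defaults with
#'   `mtry = floor(sqrt(p))`).
#' @name personalized_models
NULL

new_risk_model <- function(family, fit = NULL, sub_schema = NULL,
                           encoded_cols = NULL, constant_risk = NULL,
                           dropped = character(), note = NULL) {
  structure(list(family = family, fit = fit, sub_schema = sub_schema,
                 encoded_cols = encoded_cols, constant_risk = constant_risk,
                 dropped = dropped, note = note),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> family ", x$family, sep = "")
  if (!is.null(x$constant_risk))
    cat(sprintf(", constant risk %.4f", x$constant_risk))
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Death-counting model
#'
#' The predicted mortality risk is the empirical death fraction among the M
#' most similar patients; features are ignored at prediction time. With M
#' equal to the whole training set this reduces to the overall training
#' mortality rate.
#'
#' @param outcomes binary 0/1 vector over the neighborhood.
#' @return A `risk_model` with `constant_risk = mean(outcomes)`.
#' @export
train_death_counting <- function(outcomes) {
  if (length(outcomes) == 0) stop("empty outcome vector")
  if (any(!outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
  new_risk_model("DC", constant_risk = sum(outcomes) / length(outcomes))
}

#' Drop predictors that are constant over a neighborhood
#'
#' Small, homogeneous neighborhoods can leave a categorical predictor with
#' a single observed level (e.g. an all-male neighborhood) or a numeric
#' predictor with zero variance; such predictors carry no information for
#' the local fit and break factor-based fitting, so they are removed before
#' training and ignored at prediction.
#'
#' @param features predictor data.frame over the neighborhood.
#' @param schema the `feature_schema` of the cohort.
#' @return List with `features` (reduced columns), `schema` (matching
#'   sub-schema) and `dropped` (names removed).
#' @export
drop_degenerate_predictors <- function(features, schema) {
  keep <- vapply(schema$entries$name, function(nm) {
    v <- features[[nm]]
    length(unique(as.character(v))) > 1
  }, logical(1))
  dropped <- schema$entries$name[!keep]
  if (!any(keep))
    return(list(features = features[, 0, drop = FALSE],
                schema = NULL, dropped = dropped))
  sub <- feature_schema(schema$entries[keep, , drop = FALSE],
                        schema$levels[intersect(names(schema$levels),
                                                schema$entries$name[keep])])
  list(features = features[, sub$entries$name, drop = FALSE],
       schema = sub, dropped = dropped)
}

#' Train a personalized model on a local training set
#'
#' Fits after degenerate-predictor dropping. If the neighborhood outcomes
#' are single-class, a constant-risk model (0 or 1) is returned without
#' fitting; if no predictors survive dropping, or logistic regression fails
#' to converge or separates, the fallback is a constant risk equal to the
#' neighborhood death rate (the DC prediction).
#'
#' @param family `"LR"`, `"DT"` or `"RF"`.
#' @param features predictor data.frame (the M neighborhood rows).
#' @param outcomes binary 0/1 vector of length `nrow(features)`.
#' @param schema the cohort `feature_schema`.
#' @param seed integer seed (used by RF).
#' @param ntree RF tree count (default 500).
#' @return A `risk_model`.
#' @export
train_local_model <- function(family, features, outcomes, schema,
                              seed = 1L, ntree = 500) {
  family <- match.arg(family, c("LR", "DT", "RF"))
  stopifnot(nrow(features) == length(outcomes))
  if (any(!outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
  dd <- drop_degenerate_predictors(features, schema)
  if (length(unique(outcomes)) < 2)
    return(new_risk_model(family, constant_risk = outcomes[1],
                          dropped = dd$dropped, note = "single-class outcome"))
  if (is.null(dd$schema))
    return(new_risk_model(family, constant_risk = mean(outcomes),
                          dropped = dd$dropped, note = "no informative predictors"))
  X <- encode_features(dd$features, dd$schema)
  nz <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, nz, drop = FALSE]
  if (ncol(X) == 0)
    return(new_risk_model(family, constant_risk = mean(outcomes),
                          dropped = dd$dropped, note = "no informative predictors"))
  yf <- factor(outcomes, levels = c(0, 1))

  if (family == "LR") {
    df <- as.data.frame(X)
    names(df) <- paste0("x", seq_len(ncol(X)))
    df$.y <- outcomes
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep || !fit$converged)
      return(new_risk_model("LR", constant_risk = mean(outcomes),
                            dropped = dd$dropped,
                            note = "separation/non-convergence fallback"))
    return(new_risk_model("LR", fit = fit, sub_schema = dd$schema,
                          encoded_cols = colnames(X), dropped = dd$dropped))
  }
  if (family == "DT") {
    df <- as.data.frame(X)
    names(df) <- paste0("x", seq_len(ncol(X)))
    df$.y <- yf
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
    return(new_risk_model("DT", fit = fit, sub_schema = dd$schema,
                          encoded_cols = colnames(X), dropped = dd$dropped))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = yf, ntree = ntree,
                                    mtry = max(1, floor(sqrt(ncol(X)))),
                                    nodesize = 1)
  new_risk_model("RF", fit = fit, sub_schema = dd$schema,
                 encoded_cols = colnames(X), dropped = dd$dropped)
}

encode_for_model <- function(model, rows) {
  feat <- if (inherits(rows, "cohort_table")) cohort_features(rows) else rows
  X <- encode_features(feat[, model$sub_schema$entries$name, drop = FALSE],
                       model$sub_schema)
  X[, model$encoded_cols, drop = FALSE]
}

#' Predict mortality risk for index rows
#'
#' @param model a `risk_model` (from [train_death_counting()],
#'   [train_local_model()] or [fit_csrf()]).
#' @param rows one or more schema-conforming predictor rows
#'   (data.frame or `cohort_table`).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, rows) {
  stopifnot(inherits(model, "risk_model"))
  n <- if (is.data.frame(rows) || inherits(rows, "cohort_table")) nrow(rows) else 1L
  if (!is.null(model$constant_risk))
    return(rep(model$constant_risk, n))
  X <- encode_for_model(model, rows)
  p <- switch(model$family,
    LR = {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      # local fits with M close to p are legitimately rank-deficient;
      # aliased terms contribute nothing to the linear predictor
      withCallingHandlers(
        as.numeric(stats::predict(model$fit, newdata = df, type = "response")),
        warning = function(w) {
          if (grepl("rank-deficient", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    },
    DT = {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      as.numeric(stats::predict(model$fit, newdata = df, type = "prob")[, "1"])
    },
    RF = as.numeric(stats::predict(model$fit, newdata = X,
                                   type = "prob")[, "1"]),
    CSRF = predict_csrf_votes(model, X),
    stop("unknown model family: ", model$family))
  pmin(pmax(p, 0), 1)
}
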