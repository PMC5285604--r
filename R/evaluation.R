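#' Cross-validation fold plan
#'
#' Random partition of `1..n` into `k` folds whose sizes differ by at most
#' one. Unstratified by default; `stratify` balances a binary outcome across
#' folds.
#'
#' @param n number of patients.
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @param stratify optional binary vector of length `n`.
#' @return A `fold_plan` with integer `assignment` of length `n`.
#' @export
make_folds <- function(n, k = 10, seed = 1L, stratify = NULL) {
  if (n < k) stop("n must be at least k")
  set.seed(seed)
  assignment <- integer(n)
  if (is.null(stratify)) {
    assignment[sample.int(n)] <- rep(seq_len(k), length.out = n)
  } else {
    stopifnot(length(stratify) == n)
    for (cls in unique(stratify)) {
      ix <- which(stratify == cls)
      assignment[ix[sample.int(length(ix))]] <-
        rep(seq_len(k), length.out = length(ix))
    }
  }
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' is scored above a randomly chosen negative, with tied scores credited
#' 0.5. Invariant under strictly increasing score transforms.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision convention: the sum over positives of the precision at
#' that positive's recall step. Tied scores are handled as a single
#' threshold block (precision evaluated at the block end, weighted by the
#' block's gain in true positives), so permutations within ties do not
#' change the value. Constant scores give the prevalence.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels; at least one positive required.
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  P <- sum(labels == 1)
  if (P == 0) stop("AUPRC undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  blocks <- cumsum(!duplicated(s))
  tp_b <- tapply(y, blocks, sum)
  n_b <- tapply(y, blocks, length)
  cum_tp <- cumsum(tp_b)
  cum_n <- cumsum(n_b)
  sum(tp_b * (cum_tp / cum_n)) / P
}

#' Mean and 95% confidence interval over cross-validation folds
#'
#' @param fold_values k per-fold metric values (k >= 2).
#' @return Named vector `(mean, lower, upper)` using the t-distribution
#'   with k-1 degrees of freedom.
#' @export
summarize_ci <- function(fold_values) {
  k <- length(fold_values)
  if (k < 2) stop("need at least 2 fold values")
  m <- mean(fold_values)
  hw <- stats::qt(0.975, k - 1) * stats::sd(fold_values) / sqrt(k)
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Paired test of best-M versus reference performance
#'
#' Two-sided paired t-test on the per-fold differences between the
#' best-performing neighborhood size and a reference condition (the maximum
#' M, or the all-training-data model), pairing by fold. When the fold
#' differences have zero variance the p-value is 1 if all are zero and an
#' exact sign test otherwise.
#'
#' @param fold_best per-fold metric at the best M.
#' @param fold_ref per-fold metric at the reference condition (same folds).
#' @return Two-sided p-value.
#' @export
compare_best_vs_all <- function(fold_best, fold_ref) {
  stopifnot(length(fold_best) == length(fold_ref))
  d <- fold_best - fold_ref
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(1)
    return(stats::binom.test(sum(d > 0), sum(d != 0))$p.value)
  }
  stats::t.test(d)$p.value
}

#' Default scaled neighborhood-size grids
#'
#' Mirrors the proportions of the full-cohort grids (death counting sweeps
#' the widest, finest range; the fitted families start higher because they
#' need enough outcome and categorical variability) scaled to the training
#' size at hand. Values above `n_train` are dropped.
#'
#' @param family `"dc"`, `"lr"`, `"dt"` or `"rf"`.
#' @param n_train training-fold size.
#' @return Increasing integer vector of M values.
#' @export
default_sweep_grid <- function(family, n_train) {
  family <- tolower(family)
  g <- switch(family,
    dc = seq(10, n_train, by = 10),
    lr = seq(max(100, round(n_train * 0.2)), n_train, by = max(50, round(n_train * 0.05))),
    rf = seq(max(100, round(n_train * 0.2)), n_train, by = max(50, round(n_train * 0.05))),
    dt = seq(max(100, round(n_train * 0.25)), n_train, by = max(50, round(n_train * 0.05))),
    stop("no default grid for family ", family))
  g[g <= n_train]
}

subset_cohort <- function(cohort, idx) {
  df <- as.data.frame(cohort)[idx, , drop = FALSE]
  suppressMessages(cohort_table(df, cohort_schema(cohort)))
}

stratified_take <- function(y, m, seed) {
  set.seed(seed)
  if (m >= length(y)) return(seq_along(y))
  pos <- which(y == 1); neg <- which(y == 0)
  m_pos <- max(1L, min(length(pos), round(m * length(pos) / length(y))))
  m_neg <- min(length(neg), m - m_pos)
  sort(c(sample(pos, m_pos), sample(neg, m_neg)))
}

#' Cross-validated neighborhood-size sweep
#'
#' The experimental harness: for each fold, an unsupervised forest is grown
#' (on the union of that fold's training and test features by default -
#' outcome labels are never used - or on training features only), the
#' similarity of every test patient to every training patient is computed
#' from terminal-node co-occurrence, and for each requested family and
#' neighborhood size M a personalized model is trained on the M most
#' similar training patients and scored on the test fold. The
#' case-specific random forest has no M grid (soft thresholding) and runs
#' once per test patient. Fold-level AUROC/AUPRC are recorded, with
#' t-based 95% confidence summaries.
#'
#' @param cohort a `cohort_table`.
#' @param families subset of `c("dc", "lr", "dt", "rf", "csrf")`.
#' @param grids named list of M vectors per family; defaults from
#'   [default_sweep_grid()].
#' @param k fold count (default 10).
#' @param seed integer seed driving folds, forests and model fits.
#' @param include_all_data also evaluate the conventional model trained on
#'   all training data (for DC this is the overall training mortality rate).
#' @param psm_control list: `ntree` (default 150), `mtry` (default all
#'   encoded predictors), `nodesize` (default 5), `scope` (`"union"` or
#'   `"train_only"`).
#' @param model_control list: `rf_ntree` (default 100), `csrf_ntree`
#'   (default 100).
#' @param test_subsample optional per-fold cap on the number of test
#'   patients scored by the fitted families (LR/DT/RF/CSRF); the subsample
#'   is outcome-stratified. DC always scores the full test fold.
#' @return A `sweep_result`: `records` (family, M, condition, fold, auroc,
#'   auprc) and `summary` (per family/condition/M mean and 95% CI).
#' @export
run_sweep <- function(cohort, families = "dc", grids = NULL, k = 10,
                      seed = 1L, include_all_data = TRUE,
                      psm_control = list(), model_control = list(),
                      test_subsample = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  families <- tolower(families)
  stopifnot(all(families %in% c("dc", "lr", "dt", "rf", "csrf")))
  pc <- utils::modifyList(list(ntree = 150, mtry = NULL, nodesize = 5,
                               scope = "union"), psm_control)
  mc <- utils::modifyList(list(rf_ntree = 100, csrf_ntree = 100), model_control)
  n <- nrow(cohort)
  y <- cohort$death_30d
  schema <- cohort_schema(cohort)
  feat <- cohort_features(cohort)
  folds <- make_folds(n, k, seed = seed)
  n_train_min <- n - max(tabulate(folds$assignment, k))

  grid_fams <- setdiff(families, "csrf")
  if (is.null(grids)) grids <- list()
  for (f in grid_fams)
    if (is.null(grids[[f]])) grids[[f]] <- default_sweep_grid(f, n_train_min)
  for (f in grid_fams) {
    g <- grids[[f]]
    if (is.unsorted(g, strictly = TRUE) || any(g < 1) || any(g > n_train_min))
      stop("infeasible M grid for family ", f,
           ": values must be strictly increasing in [1, ", n_train_min, "]")
    grids[[f]] <- as.integer(g)
  }

  records <- list()
  add_rec <- function(family, M, condition, fold, scores, labels) {
    records[[length(records) + 1]] <<- data.frame(
      family = family, M = M, condition = condition, fold = fold,
      auroc = auroc(scores, labels), auprc = auprc(scores, labels))
  }

  for (fold in seq_len(k)) {
    te <- which(folds$assignment == fold)
    tr <- setdiff(seq_len(n), te)
    if (length(unique(y[te])) < 2)
      stop("single-class test fold ", fold, "; use a different seed or k")
    fold_seed <- seed + 1000L * fold

    forest_rows <- if (pc$scope == "union") seq_len(n) else tr
    forest <- fit_unsupervised_forest(subset_cohort(cohort, forest_rows),
                                      ntree = pc$ntree, mtry = pc$mtry,
                                      nodesize = pc$nodesize,
                                      seed = fold_seed)
    nodes_all <- terminal_node_ids(forest, feat)
    prox <- proximity(nodes_all[te, , drop = FALSE],
                      nodes_all[tr, , drop = FALSE])
    y_tr <- y[tr]
    ords <- lapply(seq_along(te), function(i)
      rank_similar(normalize_psm(prox[i, ]), length(tr)))

    if ("dc" %in% families) {
      cums <- vapply(ords, function(o) cumsum(y_tr[o]), numeric(length(tr)))
      for (M in grids$dc)
        add_rec("dc", M, "M", fold, cums[M, ] / M, y[te])
      if (include_all_data)
        add_rec("dc", NA, "all_data", fold, rep(mean(y_tr), length(te)), y[te])
    }

    fit_fams <- intersect(families, c("lr", "dt", "rf"))
    if (length(fit_fams) || "csrf" %in% families) {
      sub <- if (is.null(test_subsample)) seq_along(te)
             else stratified_take(y[te], test_subsample, fold_seed + 1L)
      te_sub <- te[sub]
      train_cohort <- subset_cohort(cohort, tr)
      for (f in fit_fams) {
        FAM <- toupper(f)
        nt <- if (f == "rf") mc$rf_ntree else 500
        for (M in grids[[f]]) {
          sc <- vapply(seq_along(te_sub), function(i) {
            nb <- ords[[sub[i]]][seq_len(M)]
            m <- train_local_model(FAM, feat[tr[nb], , drop = FALSE],
                                   y_tr[nb], schema,
                                   seed = fold_seed + i, ntree = nt)
            predict_risk(m, feat[te_sub[i], , drop = FALSE])
          }, numeric(1))
          add_rec(f, M, "M", fold, sc, y[te_sub])
        }
        if (include_all_data) {
          m_all <- train_local_model(FAM, feat[tr, , drop = FALSE], y_tr,
                                     schema, seed = fold_seed, ntree = nt)
          add_rec(f, NA, "all_data", fold,
                  predict_risk(m_all, feat[te_sub, , drop = FALSE]), y[te_sub])
        }
      }
      if ("csrf" %in% families) {
        sc <- vapply(seq_along(te_sub), function(i) {
          w <- normalize_psm(prox[sub[i], ])
          m <- fit_csrf(train_cohort, w,
                        csrf_config(ntree = mc$csrf_ntree,
                                    seed = fold_seed + i))
          predict_risk(m, feat[te_sub[i], , drop = FALSE])
        }, numeric(1))
        add_rec("csrf", NA, "all_data", fold, sc, y[te_sub])
      }
    }
  }

  records <- do.call(rbind, records)
  summary <- do.call(rbind, lapply(
    split(records, list(records$family, records$condition, records$M),
          drop = TRUE),
    function(g) {
      ra <- summarize_ci(g$auroc); rp <- summarize_ci(g$auprc)
      data.frame(family = g$family[1], M = g$M[1], condition = g$condition[1],
                 auroc_mean = ra["mean"], auroc_lower = ra["lower"],
                 auroc_upper = ra["upper"], auprc_mean = rp["mean"],
                 auprc_lower = rp["lower"], auprc_upper = rp["upper"])
    }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$family, summary$M, na.last = TRUE), ]
  structure(list(records = records, summary = summary, grids = grids,
                 k = k, seed = seed, psm_control = pc, model_control = mc),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(unique(x$records$family)), " families, k = ",
      x$k, ", ", nrow(x$records), " fold records\n", sep = "")
  invisible(x)
}

#' Locate the best neighborhood size and test it against the reference
#'
#' "Best" is the M with the maximum mean metric over the grid. The paired
#' comparison is against the largest M in the grid (the closest condition
#' to using all training data); the all-training-data condition is also
#' compared when present.
#'
#' @param sweep a `sweep_result`.
#' @param family one family present in the sweep.
#' @param metric `"auroc"` or `"auprc"`.
#' @return List: `M_best`, `best_mean`, `ref_mean`, `improvement`
#'   (best - max-M mean), `p_value` (paired, vs max M), and
#'   `p_value_vs_all` (vs the all-data condition, `NA` if absent).
#' @export
find_peak <- function(sweep, family, metric = c("auroc", "auprc")) {
  metric <- match.arg(metric)
  rec <- sweep$records[sweep$records$family == tolower(family), ]
  if (!nrow(rec)) stop("family not present in sweep")
  grid_rec <- rec[rec$condition == "M", ]
  means <- tapply(grid_rec[[metric]], grid_rec$M, mean)
  Ms <- as.numeric(names(means))
  M_best <- Ms[which.max(means)]
  M_max <- max(Ms)
  by_fold <- function(M) {
    g <- grid_rec[grid_rec$M == M, ]
    g[[metric]][order(g$fold)]
  }
  fb <- by_fold(M_best); fr <- by_fold(M_max)
  p_all <- NA_real_
  all_rec <- rec[rec$condition == "all_data", ]
  if (nrow(all_rec))
    p_all <- compare_best_vs_all(fb, all_rec[[metric]][order(all_rec$fold)])
  list(M_best = M_best, best_mean = mean(fb), ref_mean = mean(fr),
       improvement = mean(fb) - mean(fr),
       p_value = compare_best_vs_all(fb, fr),
       p_value_vs_all = p_all)
}
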