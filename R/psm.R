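#' Build the two-class contrast data for an unsupervised forest
#'
#' The unsupervised forest is trained to discriminate the observed rows from
#' an equally sized synthetic sample in which every feature is drawn
#' independently from its own empirical marginal. The synthetic rows share
#' each feature's marginal distribution but break all between-feature
#' dependence, so the forest's splits encode the dependence structure of the
#' observed data.
#'
#' @param cohort a `cohort_table` (outcome ignored) or predictor data.frame.
#' @param seed integer seed for the marginal resampling.
#' @return List with `features` (2n predictor rows, originals first) and
#'   `class` (factor `original`/`synthetic`).
#' @export
make_contrast_data <- function(cohort, seed = 1L) {
  feat <- if (inherits(cohort, "cohort_table")) cohort_features(cohort) else cohort
  n <- nrow(feat)
  if (n < 2) stop("need at least 2 rows to build contrast data")
  set.seed(seed)
  synth <- feat
  for (j in seq_along(synth))
    synth[[j]] <- feat[[j]][sample.int(n, n, replace = TRUE)]
  list(features = rbind(feat, synth),
       class = factor(rep(c("original", "synthetic"), each = n)))
}

#' Grow the unsupervised random forest behind the patient similarity metric
#'
#' Fits a classification forest on original-vs-synthetic contrast data with
#' `mtry` equal to the total number of (encoded) predictors, a minimum
#' terminal node size of 5 and 500 trees by default. Only the observed rows
#' are used downstream: similarity between two patients is how often they
#' share a terminal node across the trees.
#'
#' @param cohort a `cohort_table`; outcome labels are never used.
#' @param ntree number of trees (default 500).
#' @param mtry candidate predictors per split; default is all encoded
#'   predictors.
#' @param nodesize minimum terminal node size (default 5).
#' @param seed integer seed.
#' @return An `unsupervised_forest` object (keeps the fitted forest, the
#'   schema and encoded column names, and the out-of-bag contrast error).
#' @export
fit_unsupervised_forest <- function(cohort, ntree = 500, mtry = NULL,
                                    nodesize = 5, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- cohort_schema(cohort)
  if (nrow(cohort) < 2 * nodesize)
    stop("cohort too small for nodesize ", nodesize)
  contrast <- make_contrast_data(cohort, seed = seed)
  x <- encode_features(contrast$features, schema)
  if (nrow(unique(x[contrast$class == "original", , drop = FALSE])) < 2)
    stop("degenerate cohort: fewer than 2 distinct feature rows")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- p
  mtry <- min(mtry, p)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = contrast$class,
                                   ntree = ntree, mtry = mtry,
                                   nodesize = nodesize,
                                   keep.forest = TRUE)
  structure(list(rf = rf, schema = schema, colnames = colnames(x),
                 ntree = ntree, mtry = mtry, nodesize = nodesize,
                 seed = seed,
                 oob_error = as.numeric(rf$err.rate[ntree, "OOB"])),
            class = "unsupervised_forest")
}

#' @export
print.unsupervised_forest <- function(x, ...) {
  cat("<unsupervised_forest> ", x$ntree, " trees, mtry ", x$mtry,
      ", nodesize ", x$nodesize,
      sprintf(", OOB contrast error %.3f\n", x$oob_error), sep = "")
  invisible(x)
}

#' Terminal-node assignments of rows in every tree
#'
#' @param forest an `unsupervised_forest`.
#' @param rows a `cohort_table` or predictor data.frame conforming to the
#'   forest's schema.
#' @return Integer matrix, one row per input row and one column per tree;
#'   entry (r, t) is the terminal node of tree t reached by row r.
#' @export
terminal_node_ids <- function(forest, rows) {
  stopifnot(inherits(forest, "unsupervised_forest"))
  feat <- if (inherits(rows, "cohort_table")) cohort_features(rows) else rows
  x <- encode_features(feat, forest$schema)
  if (!identical(colnames(x), forest$colnames))
    stop("rows do not conform to the forest's schema")
  pred <- stats::predict(forest$rf, newdata = x, nodes = TRUE)
  nodes <- attr(pred, "nodes")
  dimnames(nodes) <- NULL
  storage.mode(nodes) <- "integer"
  nodes
}

#' Proximity counts between index and reference rows
#'
#' `Prox[i, j]` is the number of trees in which index row i and reference
#' row j fall in the same terminal node. Computed per tree through sparse
#' leaf-membership indicators, so only the requested index-by-reference
#' block is ever materialized (never the full reference-by-reference matrix
#' when only index-versus-training blocks are needed).
#'
#' @param nodes_index node-id matrix for the index rows
#'   (from [terminal_node_ids()]).
#' @param nodes_ref node-id matrix for the reference rows, same tree count.
#' @return Integer matrix of co-occurrence counts in `[0, ntree]`.
#' @export
proximity <- function(nodes_index, nodes_ref) {
  if (ncol(nodes_index) != ncol(nodes_ref))
    stop("tree count mismatch between node-id matrices")
  T_ <- ncol(nodes_index)
  # (tree, node) pairs become unique integer keys
  K <- max(max(nodes_index), max(nodes_ref)) + 1L
  offs <- (seq_len(T_) - 1L) * K
  key_i <- sweep(nodes_index, 2, offs, "+")
  key_r <- sweep(nodes_ref, 2, offs, "+")
  keys <- sort(unique(c(as.integer(key_i), as.integer(key_r))))
  Si <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(key_i)), times = T_),
    j = match(as.integer(key_i), keys),
    x = 1, dims = c(nrow(key_i), length(keys)))
  Sr <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(key_r)), times = T_),
    j = match(as.integer(key_r), keys),
    x = 1, dims = c(nrow(key_r), length(keys)))
  out <- as.matrix(Si %*% Matrix::t(Sr))
  storage.mode(out) <- "integer"
  out
}

#' Normalize one proximity row into patient similarity weights
#'
#' Divides the co-occurrence counts by the row sum (optionally after zeroing
#' a self-index), giving nonnegative weights that sum to 1 - the form needed
#' when the similarity weights act as a bootstrap sampling distribution.
#' Dividing by the tree count instead is available via `denominator`; the
#' two choices are positive multiples of each other, so any similarity
#' ranking is identical under either.
#'
#' @param prox_row numeric vector of nonnegative co-occurrence counts.
#' @param exclude optional index (e.g. the patient itself) whose count is
#'   zeroed before normalization.
#' @param denominator `"rowsum"` (default; weights sum to 1) or `"ntree"`.
#' @param ntree tree count, required for `denominator = "ntree"`.
#' @return Numeric weight vector aligned with `prox_row`.
#' @export
normalize_psm <- function(prox_row, exclude = NULL,
                          denominator = c("rowsum", "ntree"), ntree = NULL) {
  denominator <- match.arg(denominator)
  if (length(prox_row) == 0) stop("empty proximity row")
  if (any(prox_row < 0)) stop("negative proximity count")
  w <- as.numeric(prox_row)
  if (!is.null(exclude)) {
    stopifnot(exclude >= 1, exclude <= length(w))
    w[exclude] <- 0
  }
  if (denominator == "ntree") {
    if (is.null(ntree)) stop("ntree required for denominator = 'ntree'")
    return(w / ntree)
  }
  s <- sum(w)
  if (s == 0) {
    warning("all-zero proximity row: falling back to uniform weights")
    m <- length(w) - length(exclude)
    w[] <- 1 / m
    if (!is.null(exclude)) w[exclude] <- 0
    return(w)
  }
  w / s
}

#' Indices of the M most similar training patients
#'
#' Hard thresholding on the similarity weights: returns the positions of the
#' M largest weights in descending weight order, ties broken by ascending
#' patient index so the selection is deterministic.
#'
#' @param psm numeric weight vector over training patients.
#' @param M neighborhood size, `1 <= M <= length(psm)`.
#' @return Integer vector of length M.
#' @export
rank_similar <- function(psm, M) {
  n <- length(psm)
  if (M < 1 || M > n) stop("M must be in [1, ", n, "]")
  ord <- order(-psm, seq_len(n))
  ord[seq_len(M)]
}

#' Cosine-similarity patient similarity metric
#'
#' Comparator metric on one-hot encoded, z-scaled features (scaling
#' statistics come from the training rows). Raw cosines are shifted by +1 to
#' be nonnegative and normalized to sum to 1 for interface parity with the
#' forest-proximity weights; the raw cosines are attached as an attribute.
#'
#' @param index_row single-row predictor data.frame (or 1-row cohort).
#' @param training_rows `cohort_table` or predictor data.frame.
#' @param schema `feature_schema`; defaults to the training cohort's schema.
#' @return Weight vector over training rows (attribute `cosine` holds the
#'   unshifted similarities).
#' @export
cosine_psm <- function(index_row, training_rows, schema = NULL) {
  if (inherits(training_rows, "cohort_table") && is.null(schema))
    schema <- cohort_schema(training_rows)
  feat_tr <- if (inherits(training_rows, "cohort_table"))
    cohort_features(training_rows) else training_rows
  feat_ix <- if (inherits(index_row, "cohort_table"))
    cohort_features(index_row) else index_row
  Xt <- encode_features(feat_tr, schema)
  xi <- encode_features(feat_ix, schema)
  mu <- colMeans(Xt); sdv <- apply(Xt, 2, stats::sd)
  keep <- sdv > 0
  Z <- sweep(sweep(Xt[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  zi <- (as.numeric(xi)[keep] - mu[keep]) / sdv[keep]
  ni <- sqrt(sum(zi^2))
  nt <- sqrt(rowSums(Z^2))
  cosv <- if (ni == 0) rep(0, nrow(Z)) else as.numeric(Z %*% zi) / (ni * pmax(nt, .Machine$double.eps))
  cosv[nt == 0] <- 0
  w <- cosv + 1
  s <- sum(w)
  w <- if (s == 0) rep(1 / length(w), length(w)) else w / s
  attr(w, "cosine") <- cosv
  w
}
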