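# Shared fixtures: cohorts are simulated once per test run and memoized.

.cohort_cache <- new.env(parent = emptyenv())

cached_sim <- function(n, effect_scale = 1, seed = 101, cluster_sep = 0.8) {
  key <- paste(n, effect_scale, seed, cluster_sep, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(simulation_config(
      n, effect_scale = effect_scale, cluster_sep = cluster_sep, seed = seed))
  .cohort_cache[[key]]
}

# brute-force proximity oracle: loop over every (pair, tree)
proximity_bruteforce <- function(nodes_index, nodes_ref) {
  out <- matrix(0L, nrow(nodes_index), nrow(nodes_ref))
  for (i in seq_len(nrow(nodes_index)))
    for (j in seq_len(nrow(nodes_ref)))
      for (t in seq_len(ncol(nodes_index)))
        if (nodes_index[i, t] == nodes_ref[j, t])
          out[i, j] <- out[i, j] + 1L
  out
}

# AUROC oracle: enumerate positive-negative pairs, ties credited 0.5
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPRC oracle: enumerate distinct score thresholds; average precision is
# the sum over threshold blocks of (gain in recall) * precision
auprc_thresholds <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_tp <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    ap <- ap + (tp - prev_tp) * prec
    prev_tp <- tp
  }
  ap / P
}
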