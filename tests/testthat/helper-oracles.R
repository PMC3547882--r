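# Independent oracles used to freeze expected values.  These deliberately
# re-derive quantities by brute force / definitional formulas, not by the
# package's own code paths.

# circular gene distance by walking both arcs step by step
oracle_circ_dist <- function(a, b, G) {
  steps_fwd <- 0L; pos <- a
  while (pos != b) { pos <- (pos + 1L) %% G; steps_fwd <- steps_fwd + 1L }
  steps_bwd <- 0L; pos <- a
  while (pos != b) { pos <- (pos - 1L) %% G; steps_bwd <- steps_bwd + 1L }
  min(steps_fwd, steps_bwd)
}

# AUC as the exhaustive Mann-Whitney U statistic with 0.5 per tie
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Pearson correlation by the definitional formula
oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# gene clusters by an independent route: symmetric adjacency (same strand,
# intergenic gap <= cutoff, including the wrap-around junction) expanded to
# connected components
oracle_clusters <- function(genome, max_gap) {
  g <- genome$genes
  n <- nrow(g)
  adj <- matrix(FALSE, n, n)
  gap_between <- function(i, j) {
    # gap walking forward from gene i to gene j (j the next gene)
    if (j == i + 1L) max(g$start[j] - g$end[i] - 1L, 0L)
    else max(genome$length_bp - g$end[i], 0L) + g$start[j] - 1L  # wrap n->1
  }
  for (i in seq_len(n)) {
    j <- if (i < n) i + 1L else 1L
    if (n > 1L && g$strand[i] == g$strand[j] && gap_between(i, j) <= max_gap) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(g$gene_id, comp)
}
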