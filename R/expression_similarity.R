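# Expression Similarity (ES): condition selection and gene-gene
# co-expression.

#' Retain the most varying expression conditions
#'
#' Conditions are ranked by the variance of their expression values across
#' genes (missing values excluded) and the top `k` are kept, ties broken by
#' condition id; column order of the retained conditions is preserved.
#' With `k` at or above the condition count the matrix is returned
#' unchanged.
#'
#' @param E numeric genes-by-conditions matrix (from
#'   [read_expression_matrix()] or [simulate_expression()])
#' @param k number of conditions to retain (default 300)
#' @return the column-subset matrix
#' @export
select_varying_conditions <- function(E, k = 300L) {
  stopifnot(is.matrix(E), k >= 2)
  if (k >= ncol(E)) return(E)
  v <- apply(E, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v)] <- -Inf
  keep <- colnames(E)[order(-v, colnames(E))][seq_len(k)]
  E[, colnames(E) %in% keep, drop = FALSE]
}

#' Expression Similarity scores
#'
#' Pearson correlation of two genes' expression profiles over the
#' conditions where both are measured, clamped below at 0.  Pairs with a
#' gene absent from the matrix, fewer than three conditions of joint
#' measurement, or a constant profile are undefined with score 0 (logged,
#' not an error).
#'
#' @param pairs two-column data.frame (or matrix) of gene/protein ids
#' @param E numeric genes-by-conditions matrix
#' @return a [pair_score_table()] with method `"ES"`
#' @export
es_scores <- function(pairs, E) {
  stopifnot(is.matrix(E))
  pairs <- normalize_pairs(pairs)
  prots <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  absent <- setdiff(prots, rownames(E))
  if (length(absent)) {
    lk_log(sprintf("es_scores: %d gene(s) absent from expression matrix; their pairs are undefined",
                   length(absent)))
  }
  inE <- intersect(prots, rownames(E))
  C <- matrix(NA_real_, length(prots), length(prots),
              dimnames = list(prots, prots))
  if (length(inE) >= 1L) {
    V <- E[inE, , drop = FALSE]
    fin <- is.finite(V)
    npair <- tcrossprod(fin * 1)  # joint finite-condition counts
    sub <- suppressWarnings(stats::cor(t(V), use = "pairwise.complete.obs"))
    sub[npair < 3L] <- NA_real_
    C[inE, inE] <- sub
  }
  score_table_from_matrix(pairs, prots, C, "ES")
}
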