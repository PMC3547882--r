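# Gold-standard construction and threshold/ROC/AUC evaluation.

new_gold_standard <- function(proteins, universe, positives, scope) {
  n_universe <- if (is.null(universe)) {
    n <- length(proteins); n * (n - 1) / 2
  } else length(universe)
  structure(list(proteins = proteins, universe = universe,
                 positives = positives, scope = scope,
                 n_universe = n_universe, n_positives = length(positives)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> scope=%s: %d proteins, %s pairs, %d positives\n",
              x$scope, length(x$proteins),
              format(x$n_universe, big.mark = ","), x$n_positives))
  invisible(x)
}

# keys of all pairs of the members of each pathway, unioned
pathway_pair_keys <- function(ann, pathways) {
  keys <- character()
  for (pw in pathways) {
    members <- sort(unique(ann$protein_id[ann$level3 == pw]))
    if (length(members) < 2L) next
    idx <- utils::combn(length(members), 2L)
    keys <- c(keys, pair_key(members[idx[1L, ]], members[idx[2L, ]]))
  }
  sort(unique(keys))
}

#' Build the global gold standard
#'
#' The universe is every unordered pair of annotated proteins; a pair is
#' positive when the two proteins share at least one level-3 pathway.
#' Sharing only a level-2 category does not make a pair positive.
#'
#' @param ann a [pathway_annotation()]
#' @return object of class `gold_standard` with scope `"global"`.  The
#'   universe is implicit (all pairs of `proteins`); `n_universe` is
#'   `choose(n, 2)`.
#' @export
build_global_gold <- function(ann) {
  stopifnot(inherits(ann, "pathway_annotation"))
  proteins <- annotated_proteins(ann)
  if (length(proteins) < 2L) {
    stop("build_global_gold: need >= 2 annotated proteins", call. = FALSE)
  }
  positives <- pathway_pair_keys(ann, unique(ann$level3))
  new_gold_standard(proteins, NULL, positives, "global")
}

#' Build a pathway-scoped gold standard
#'
#' The pair universe is shared by every category: all pairs sharing at
#' least one level-3 pathway whose level-2 category is in
#' `selected_categories`.  Positives are the pairs sharing a level-3
#' pathway belonging to `category`; all other universe pairs are
#' negatives.  Because the universe is category-independent, positives +
#' negatives is the same total for every category.
#'
#' @param ann a [pathway_annotation()]
#' @param category the level-2 category under evaluation
#' @param selected_categories level-2 categories defining the benchmark
#'   (default: all categories in `ann`)
#' @return object of class `gold_standard` with scope `"pathway:<category>"`
#' @export
build_pathway_gold <- function(ann, category, selected_categories = NULL) {
  stopifnot(inherits(ann, "pathway_annotation"))
  selected_categories <- selected_categories %||% sort(unique(ann$level2))
  if (!category %in% selected_categories) {
    stop(sprintf("build_pathway_gold: unknown category '%s'", category),
         call. = FALSE)
  }
  ann_sel <- ann[ann$level2 %in% selected_categories, , drop = FALSE]
  universe <- pathway_pair_keys(ann_sel, unique(ann_sel$level3))
  pos_paths <- unique(ann_sel$level3[ann_sel$level2 == category])
  positives <- pathway_pair_keys(ann_sel, pos_paths)
  proteins <- sort(unique(ann_sel$protein_id))
  new_gold_standard(proteins, universe, positives,
                    paste0("pathway:", category))
}

# score + label vectors over the gold universe; every universe pair must be
# scored.
gold_vectors <- function(scores, gold) {
  stopifnot(inherits(scores, "pair_score_table"),
            inherits(gold, "gold_standard"))
  skey <- pair_key(scores$protein_a, scores$protein_b)
  ukey <- gold$universe %||% {
    n <- length(gold$proteins)
    idx <- utils::combn(n, 2L)
    pair_key(gold$proteins[idx[1L, ]], gold$proteins[idx[2L, ]])
  }
  m <- match(ukey, skey)
  if (anyNA(m)) {
    miss <- ukey[is.na(m)]
    stop(sprintf("evaluation: %d universe pair(s) missing from scores, e.g. %s",
                 length(miss),
                 paste(sub("\x1f", "/", utils::head(miss, 3)), collapse = "; ")),
         call. = FALSE)
  }
  list(score = scores$score[m], label = ukey %in% gold$positives)
}

#' Confusion counts at a score threshold
#'
#' Pairs scoring `>= t` are predicted positive.  True/false positives and
#' negatives are counted against the gold standard over its full pair
#' universe.
#'
#' @param scores a [pair_score_table()] covering the gold universe
#' @param gold a `gold_standard`
#' @param t score threshold
#' @return list with `tp`, `fp`, `fn`, `tn`, `threshold`
#' @export
confusion_at_threshold <- function(scores, gold, t) {
  v <- gold_vectors(scores, gold)
  called <- v$score >= t
  list(tp = sum(called & v$label), fp = sum(called & !v$label),
       fn = sum(!called & v$label), tn = sum(!called & !v$label),
       threshold = t)
}

#' ROC curve and AUC
#'
#' Thresholds sweep the distinct observed scores in descending order; each
#' tied block contributes a single step (a diagonal segment), so the
#' trapezoidal AUC equals the Mann-Whitney statistic with ties counted
#' one-half.  The curve is anchored at (0,0) and (1,1).
#'
#' @param scores a [pair_score_table()] covering the gold universe
#' @param gold a `gold_standard` with at least one positive and one
#'   negative pair
#' @return object of class `roc_result`: list with `points` (data.frame of
#'   `threshold`, `fpr`, `tpr`) and `auc`
#' @export
roc_curve <- function(scores, gold) {
  v <- gold_vectors(scores, gold)
  P <- sum(v$label); N <- sum(!v$label)
  if (P == 0L || N == 0L) {
    stop("roc_curve: gold standard must contain positives and negatives",
         call. = FALSE)
  }
  o <- order(v$score, decreasing = TRUE)
  s <- v$score[o]; y <- v$label[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(s, fromLast = TRUE))  # end of each tied block
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / N),
                    tpr = c(0, tp[last] / P))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' True/false positive counts along a threshold series
#'
#' @param scores a [pair_score_table()] covering the gold universe
#' @param gold a `gold_standard`
#' @param thresholds ascending numeric thresholds
#' @return data.frame with columns `threshold`, `tp`, `fp`
#' @export
tp_fp_series <- function(scores, gold, thresholds) {
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("tp_fp_series: thresholds must be sorted ascending", call. = FALSE)
  }
  v <- gold_vectors(scores, gold)
  do.call(rbind, lapply(thresholds, function(t) {
    called <- v$score >= t
    data.frame(threshold = t, tp = sum(called & v$label),
               fp = sum(called & !v$label))
  }))
}

#' AUC summary matrix across methods and categories
#'
#' One ROC/AUC per (category gold standard, method score table), arranged
#' with categories as rows and methods as columns, plus an `Average` column
#' (per-category mean over methods) and an `Average` row (per-method mean
#' over categories) computed from the unrounded AUCs.
#'
#' @param score_tables named list of [pair_score_table()] objects (names =
#'   method labels)
#' @param golds named list of `gold_standard` objects (names = category
#'   labels)
#' @return numeric matrix of AUCs with the `Average` margins
#' @export
auc_summary <- function(score_tables, golds) {
  stopifnot(length(score_tables) >= 1L, length(golds) >= 1L)
  M <- matrix(NA_real_, length(golds), length(score_tables),
              dimnames = list(names(golds), names(score_tables)))
  for (g in names(golds)) {
    for (m in names(score_tables)) {
      M[g, m] <- roc_curve(score_tables[[m]], golds[[g]])$auc
    }
  }
  out <- cbind(M, Average = rowMeans(M))
  rbind(out, Average = colMeans(out))
}
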