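# Phylogenetic Profiling (PP): reference-genome dereplication, bit-score
# profile matrix, divergence normalization, and profile correlation.

#' Dereplicate the reference genome set
#'
#' Near-redundant genomes inflate profile correlations, so genomes whose
#' query-ortholog sets overlap by more than `overlap_threshold` (shared
#' count over the smaller set) are clustered by single linkage and a single
#' representative per cluster is kept: the genome with the largest ortholog
#' set, ties broken lexicographically by genome id.
#'
#' @param omap an [ortholog_map()]
#' @param query_protein_ids query proteins whose orthologs define the
#'   per-genome ortholog sets
#' @param overlap_threshold overlap fraction above which two genomes are
#'   linked (default 0.90)
#' @return sorted character vector of representative genome ids
#' @export
select_reference_genomes <- function(omap, query_protein_ids,
                                     overlap_threshold = 0.90) {
  stopifnot(inherits(omap, "ortholog_map"))
  genomes <- sort(names(omap$genome_protein_counts))
  if (!length(genomes)) stop("select_reference_genomes: no genomes in map",
                             call. = FALSE)
  ent <- omap$entries[omap$entries$query_id %in% query_protein_ids, ]
  # presence matrix: proteins x genomes
  prots <- sort(unique(ent$query_id))
  M <- matrix(FALSE, length(prots), length(genomes),
              dimnames = list(prots, genomes))
  M[cbind(match(ent$query_id, prots), match(ent$genome_id, genomes))] <- TRUE
  sizes <- colSums(M)
  shared <- crossprod(M)  # genomes x genomes shared-ortholog counts
  mins <- outer(sizes, sizes, pmin)
  ov <- ifelse(mins > 0, shared / mins, 0)
  # single-linkage connected components over edges ov > threshold
  n <- length(genomes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (ov[i, j] > overlap_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), comp), function(ix) {
    ix <- ix[order(-sizes[ix], genomes[ix])]
    genomes[ix[1L]]
  }, character(1))
  sort(unname(reps))
}

#' Build the phylogenetic profile matrix
#'
#' Rows are query proteins, columns reference genomes; entry (i,j) is the
#' alignment bit score of protein i against its ortholog in genome j, or 0
#' when no ortholog exists.
#'
#' @param omap an [ortholog_map()]
#' @param query_protein_ids row protein ids
#' @param genome_ids column genome ids (must be known to the map)
#' @return object of class `profile_matrix`: a list with `values` (matrix),
#'   and `normalized` (logical)
#' @export
build_profile_matrix <- function(omap, query_protein_ids, genome_ids) {
  stopifnot(inherits(omap, "ortholog_map"))
  query_protein_ids <- unique(as.character(query_protein_ids))
  genome_ids <- unique(as.character(genome_ids))
  unknown <- setdiff(genome_ids, names(omap$genome_protein_counts))
  if (length(unknown)) {
    stop(sprintf("build_profile_matrix: unknown genome(s): %s",
                 paste(unknown, collapse = ",")), call. = FALSE)
  }
  V <- matrix(0, length(query_protein_ids), length(genome_ids),
              dimnames = list(query_protein_ids, genome_ids))
  ent <- omap$entries
  keep <- ent$query_id %in% query_protein_ids & ent$genome_id %in% genome_ids
  ent <- ent[keep, , drop = FALSE]
  V[cbind(match(ent$query_id, query_protein_ids),
          match(ent$genome_id, genome_ids))] <- ent$bit_score
  missing <- setdiff(query_protein_ids, unique(omap$entries$query_id))
  if (length(missing)) {
    warning(sprintf("build_profile_matrix: no orthologs for %d protein(s); zero rows emitted",
                    length(missing)), call. = FALSE)
  }
  structure(list(values = V, normalized = FALSE), class = "profile_matrix")
}

#' Normalize a profile matrix for protein and species divergence
#'
#' Two-step correction: (1) protein divergence - every nonzero cell is
#' divided by that protein's self-alignment bit score, putting slow and
#' fast evolving proteins on a common relative-similarity scale; (2)
#' species divergence - every column is divided by the mean of its nonzero
#' entries, removing the genome-wide tendency of distant species to yield
#' uniformly low scores.  Columns without any ortholog stay zero.
#'
#' @param P an unnormalized `profile_matrix` from [build_profile_matrix()]
#' @param omap the [ortholog_map()] supplying self bit scores
#' @return the normalized `profile_matrix`
#' @export
normalize_profile_matrix <- function(P, omap) {
  stopifnot(inherits(P, "profile_matrix"), inherits(omap, "ortholog_map"))
  if (isTRUE(P$normalized)) {
    stop("normalize_profile_matrix: matrix already normalized", call. = FALSE)
  }
  V <- P$values
  prots <- rownames(V)
  ent <- omap$entries
  selfbit <- vapply(prots, function(p) {
    s <- ent$self_bit_score[ent$query_id == p]
    if (length(s)) s[[1L]] else NA_real_
  }, numeric(1))
  active <- rowSums(V != 0) > 0
  if (any(active & !is.finite(selfbit))) {
    stop(sprintf("normalize_profile_matrix: missing self bit score for %s",
                 paste(prots[active & !is.finite(selfbit)], collapse = ",")),
         call. = FALSE)
  }
  sb <- ifelse(is.finite(selfbit), selfbit, 1)
  V <- V / sb  # row-wise; zeros stay zero
  cm <- apply(V, 2L, function(col) {
    nz <- col != 0
    if (any(nz)) mean(col[nz]) else 1
  })
  V <- sweep(V, 2L, cm, "/")
  structure(list(values = V, normalized = TRUE), class = "profile_matrix")
}

#' Phylogenetic Profiling scores
#'
#' Pearson correlation of the two proteins' full normalized profile rows
#' (zeros included), clamped below at 0 to stay on the 0-1 reporting
#' scale.  A protein whose profile has zero variance across genomes cannot
#' be correlated; its pairs are undefined with score 0.
#'
#' @param pairs two-column data.frame (or matrix) of query protein ids
#' @param P a normalized `profile_matrix`
#' @return a [pair_score_table()] with method `"PP"`
#' @export
pp_scores <- function(pairs, P) {
  stopifnot(inherits(P, "profile_matrix"))
  if (!isTRUE(P$normalized)) {
    stop("pp_scores: profile matrix must be normalized first", call. = FALSE)
  }
  pairs <- normalize_pairs(pairs)
  prots <- rownames(P$values)
  missing <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)), prots)
  if (length(missing)) {
    stop(sprintf("pp_scores: protein(s) absent from profile matrix: %s",
                 paste(utils::head(missing, 5), collapse = ",")),
         call. = FALSE)
  }
  # all-pairs PCC in one pass; zero-variance rows yield NA -> undefined
  C <- suppressWarnings(stats::cor(t(P$values)))
  score_table_from_matrix(pairs, prots, C, "PP")
}
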