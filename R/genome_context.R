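# Gene Neighbor (GN) and Gene Cluster (GC) scorers: functional linkage
# inferred from conserved chromosomal context of orthologous genes in
# reference genomes.

#' Circular gene-rank distance
#'
#' Distance between two genes on a circular chromosome measured in gene
#' ranks (number of intervening genes + 1), taking the shorter arc.
#'
#' @param rank_a,rank_b 0-based gene ranks, `rank_a != rank_b`
#' @param genome_size number of genes G on the chromosome (>= 2)
#' @return integer in `[1, floor(G/2)]`
#' @export
gene_rank_distance <- function(rank_a, rank_b, genome_size) {
  stopifnot(genome_size >= 2)
  if (any(rank_a < 0 | rank_a >= genome_size) ||
      any(rank_b < 0 | rank_b >= genome_size)) {
    stop("gene_rank_distance: ranks must be in [0, G)", call. = FALSE)
  }
  if (any(rank_a == rank_b)) {
    stop("gene_rank_distance: self-distance undefined (equal ranks)",
         call. = FALSE)
  }
  d <- abs(rank_a - rank_b)
  pmin(d, genome_size - d)
}

# For one genome, resolve the chromosomal rank of each query protein's
# ortholog.  Returns an integer vector indexed like `proteins` with NA for
# proteins lacking an ortholog in this genome.  An ortholog gene id missing
# from the genome table is a hard error: the inputs disagree.
ortholog_ranks <- function(proteins, entries_g, genome) {
  hit <- match(proteins, entries_g$query_id)
  ranks <- rep(NA_integer_, length(proteins))
  has <- !is.na(hit)
  if (any(has)) {
    gid <- entries_g$ortholog_gene_id[hit[has]]
    pos <- match(gid, genome$genes$gene_id)
    if (anyNA(pos)) {
      miss <- gid[is.na(pos)][1L]
      stop(sprintf("gene id '%s' not found in genome table '%s'",
                   miss, genome$genome_id), call. = FALSE)
    }
    ranks[has] <- genome$genes$rank[pos]
  }
  ranks
}

#' Gene Neighbor interaction scores
#'
#' For each protein pair the minimum chromosomal distance between the genes
#' encoding their orthologs is taken over all reference genomes in which
#' both orthologs occur, irrespective of gene orientation.  Distances are
#' measured in gene ranks on the circular chromosome and normalized by
#' `floor(G/2)` so they lie in (0,1]; the minimum normalized distance is
#' subtracted from one, turning it into a similarity score.  Pairs whose
#' orthologs never co-occur in any reference genome are undefined and carry
#' score 0.
#'
#' @param pairs two-column data.frame (or matrix) of query protein ids
#' @param omap an [ortholog_map()]
#' @param genomes list of [genome_table()] objects (the reference set)
#' @return a [pair_score_table()] with method `"GN"`
#' @export
gn_scores <- function(pairs, omap, genomes) {
  stopifnot(inherits(omap, "ortholog_map"))
  pairs <- normalize_pairs(pairs)
  best <- rep(Inf, nrow(pairs))
  seen <- rep(FALSE, nrow(pairs))
  ent <- omap$entries
  proteins <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  ia <- match(pairs$protein_a, proteins)
  ib <- match(pairs$protein_b, proteins)
  for (genome in genomes) {
    stopifnot(inherits(genome, "genome_table"))
    eg <- ent[ent$genome_id == genome$genome_id, , drop = FALSE]
    if (!nrow(eg)) next
    ranks <- ortholog_ranks(proteins, eg, genome)
    G <- nrow(genome$genes)
    if (G < 2L) next
    ra <- ranks[ia]; rb <- ranks[ib]
    both <- !is.na(ra) & !is.na(rb)
    same <- both & ra == rb
    if (any(same)) {
      lk_log(sprintf("gn_scores: %d pair(s) map to the same gene in %s; contribution skipped",
                     sum(same), genome$genome_id), level = "debug")
    }
    use <- both & ra != rb
    if (!any(use)) next
    d <- abs(ra[use] - rb[use])
    d <- pmin(d, G - d)
    nd <- d / (G %/% 2L)
    best[use] <- pmin(best[use], nd)
    seen <- seen | use
  }
  und <- !seen
  sc <- ifelse(und, 0, 1 - best)
  sc <- pmin(pmax(sc, 0), 1)
  pair_score_table(pairs$protein_a, pairs$protein_b, sc, und, method = "GN")
}

#' Detect operon-like gene clusters on one genome
#'
#' A gene cluster is a maximal run of co-directional genes whose
#' consecutive intergenic gaps are all `<= max_gap` nucleotides.  The gap
#' between consecutive genes is `start(next) - end(prev) - 1`; overlapping
#' genes count as gap 0.  Because the chromosome is circular, the junction
#' between the last and first gene is evaluated too and the two terminal
#' clusters are merged when they are co-directional and close enough.
#'
#' @param genome a [genome_table()]
#' @param max_gap inclusive intergenic-gap cutoff in nt (default 100)
#' @return list of clusters, each a list with `genome_id`, `strand`,
#'   `members` (gene ids in chromosomal walk order) and `span`
#' @export
detect_gene_clusters <- function(genome, max_gap = 100L) {
  stopifnot(inherits(genome, "genome_table"), max_gap >= 0)
  cid <- cluster_assignment(genome, max_gap)
  g <- genome$genes
  out <- lapply(split(seq_len(nrow(g)), cid), function(ix) {
    # walk order: for a wrapped cluster the members at the chromosome end
    # precede those at the start
    if (length(ix) > 1L && any(diff(ix) > 1L)) {
      brk <- which(diff(ix) > 1L) + 1L
      ix <- c(ix[brk:length(ix)], ix[1:(brk - 1L)])
    }
    list(genome_id = genome$genome_id,
         strand = g$strand[ix[1L]],
         members = g$gene_id[ix],
         span = c(g$start[ix[1L]], g$end[ix[length(ix)]]))
  })
  names(out) <- NULL
  out
}

# Cluster id per gene (integer vector aligned with genome$genes rows, which
# are in rank order).  Shared by detect_gene_clusters and gc_scores.
cluster_assignment <- function(genome, max_gap = 100L) {
  g <- genome$genes
  n <- nrow(g)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  gap <- pmax(g$start[-1L] - g$end[-n] - 1L, 0L)
  brk <- g$strand[-1L] != g$strand[-n] | gap > max_gap
  cid <- cumsum(c(TRUE, brk))
  # circular wrap: join last cluster to first when co-directional and the
  # gap across the origin is within the cutoff
  if (cid[n] > 1L) {
    wrap_gap <- max(genome$length_bp - g$end[n], 0L) + g$start[1L] - 1L
    if (g$strand[1L] == g$strand[n] && wrap_gap <= max_gap) {
      lk_log(sprintf("cluster_assignment: wrap-around cluster joined in %s",
                     genome$genome_id), level = "debug")
      cid[cid == cid[n]] <- 1L
      cid <- match(cid, sort(unique(cid)))
    }
  }
  cid
}

#' Gene Cluster interaction scores
#'
#' Co-occurrence probability of two proteins' orthologs inside the same
#' operon-like gene cluster: the number of reference genomes in which the
#' two orthologs lie in one cluster divided by the number of reference
#' genomes in which both orthologs are present.  Pairs never co-present in
#' any reference genome are undefined with score 0.
#'
#' @inheritParams gn_scores
#' @param max_gap intergenic-gap cutoff passed to [detect_gene_clusters()]
#' @return a [pair_score_table()] with method `"GC"`
#' @export
gc_scores <- function(pairs, omap, genomes, max_gap = 100L) {
  stopifnot(inherits(omap, "ortholog_map"))
  pairs <- normalize_pairs(pairs)
  ent <- omap$entries
  proteins <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  ia <- match(pairs$protein_a, proteins)
  ib <- match(pairs$protein_b, proteins)
  n_same <- integer(nrow(pairs))
  n_both <- integer(nrow(pairs))
  for (genome in genomes) {
    stopifnot(inherits(genome, "genome_table"))
    eg <- ent[ent$genome_id == genome$genome_id, , drop = FALSE]
    if (!nrow(eg)) next
    ranks <- ortholog_ranks(proteins, eg, genome)
    cid <- cluster_assignment(genome, max_gap)
    pc <- ifelse(is.na(ranks), NA_integer_, cid[ranks + 1L])
    ca <- pc[ia]; cb <- pc[ib]
    ra <- ranks[ia]; rb <- ranks[ib]
    both <- !is.na(ca) & !is.na(cb) & ra != rb
    n_both <- n_both + both
    n_same <- n_same + (both & ca == cb)
  }
  und <- n_both == 0L
  sc <- ifelse(und, 0, n_same / pmax(n_both, 1L))
  pair_score_table(pairs$protein_a, pairs$protein_b, sc, und, method = "GC")
}
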