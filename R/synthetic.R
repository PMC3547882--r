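# Synthetic comparative-genomics worlds: species tree, presence/absence
# profiles with bit scores, circular gene orders, an expression compendium,
# per-protein distance matrices and a two-level pathway annotation, plus
# ground-truth linkage labels.  Each signal channel (co-inheritance,
# operon, co-expression, co-evolution) is generated independently so a
# scorer's recovery can be attributed to its own channel.

#' Configuration of a synthetic world
#'
#' Counts default to a world large enough for stable AUCs but small enough
#' for seconds-scale runs: 60 genomes, 200 proteins organized as 4
#' categories x 3 pathways x 16 proteins (the remaining proteins are
#' unannotated background), and a 380-condition expression compendium.
#' Signal knobs are mixing weights in `[0,1]`; at 0 the corresponding
#' structure is absent, at 1 it is deterministic.
#'
#' @param n_genomes number of reference genomes (>= 3)
#' @param n_proteins number of query proteins
#' @param n_categories level-2 categories
#' @param pathways_per_category level-3 pathways per category
#' @param proteins_per_pathway proteins per pathway;
#'   `n_categories * pathways_per_category * proteins_per_pathway` must not
#'   exceed `n_proteins`
#' @param n_conditions expression conditions (default 380)
#' @param co_inheritance probability that a pathway member inherits each
#'   entry of its pathway's presence vector instead of resampling it
#' @param operon_prob probability that a pathway's co-present genes form an
#'   operon-like block in a given genome
#' @param coexpression weight of the shared pathway expression program
#' @param coevolution weight of the shared residual added to pathway
#'   members' distance matrices
#' @param profile_flip_rate per-entry presence flip noise
#' @param expr_sigma expression measurement noise (sd)
#' @param dist_sigma distance-matrix measurement noise (sd)
#' @param seed mandatory integer RNG seed
#' @return object of class `world_config`
#' @export
world_config <- function(n_genomes = 60L, n_proteins = 200L,
                         n_categories = 4L, pathways_per_category = 3L,
                         proteins_per_pathway = 16L, n_conditions = 380L,
                         co_inheritance = 0.9, operon_prob = 0.9,
                         coexpression = 0.9, coevolution = 0.9,
                         profile_flip_rate = 0.1, expr_sigma = 0.5,
                         dist_sigma = 0.05, seed) {
  if (missing(seed)) stop("world_config: seed is mandatory", call. = FALSE)
  cfg <- list(n_genomes = as.integer(n_genomes),
              n_proteins = as.integer(n_proteins),
              n_categories = as.integer(n_categories),
              pathways_per_category = as.integer(pathways_per_category),
              proteins_per_pathway = as.integer(proteins_per_pathway),
              n_conditions = as.integer(n_conditions),
              co_inheritance = co_inheritance, operon_prob = operon_prob,
              coexpression = coexpression, coevolution = coevolution,
              profile_flip_rate = profile_flip_rate,
              expr_sigma = expr_sigma, dist_sigma = dist_sigma,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genomes >= 3, n_proteins >= 2, n_categories >= 1,
              pathways_per_category >= 1, proteins_per_pathway >= 2,
              n_conditions >= 2, expr_sigma >= 0, dist_sigma >= 0)
    for (k in c(co_inheritance, operon_prob, coexpression, coevolution,
                profile_flip_rate)) {
      stopifnot(k >= 0, k <= 1)
    }
    if (n_categories * pathways_per_category * proteins_per_pathway >
        n_proteins) {
      stop("world_config: pathway layout exceeds n_proteins", call. = FALSE)
    }
  })
  cfg$hash <- object_hash(cfg)
  structure(cfg, class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config>\n")
  for (k in setdiff(names(x), "hash")) cat(sprintf("  %s: %s\n", k, x[[k]]))
  cat(sprintf("  hash: %s\n", x$hash))
  invisible(x)
}

#' Deterministic pathway layout of a world
#'
#' Assigns the first `n_categories * pathways_per_category *
#' proteins_per_pathway` proteins to pathways in id order; remaining
#' proteins are unannotated background.  No randomness.
#'
#' @param config a [world_config()]
#' @return a [pathway_annotation()]
#' @export
pathway_layout <- function(config) {
  stopifnot(inherits(config, "world_config"))
  prots <- sprintf("P%04d", seq_len(config$n_proteins))
  rows <- list(); k <- 0L
  for (ci in seq_len(config$n_categories)) {
    cat_id <- sprintf("C%02d", ci)
    for (pi in seq_len(config$pathways_per_category)) {
      pw_id <- sprintf("%s_pw%02d", cat_id, pi)
      members <- prots[k + seq_len(config$proteins_per_pathway)]
      k <- k + config$proteins_per_pathway
      rows[[pw_id]] <- data.frame(protein_id = members, level2 = cat_id,
                                  level3 = pw_id, stringsAsFactors = FALSE)
    }
  }
  pathway_annotation(do.call(rbind, rows))
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree with `n_genomes` tips labeled `g001...`, branch
#' lengths from the constant-rate birth process.  Deterministic under
#' `seed`.
#'
#' @param n_genomes number of tips (>= 3)
#' @param seed integer seed
#' @return an `ape::phylo` tree
#' @export
simulate_species_tree <- function(n_genomes, seed) {
  if (n_genomes < 3L) stop("simulate_species_tree: need n >= 3", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_genomes, birth = 1, death = 0)
  tree$tip.label <- sprintf("g%03d", seq_len(n_genomes))
  tree
}

# patristic distances scaled to max 1
tree_distances <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  D / max(D)
}

#' Simulate presence/absence profiles with bit scores
#'
#' Presence is phylogenetically autocorrelated along the species tree, the
#' structure that makes shared-ortholog genome distances track speciation:
#' every presence vector (one base vector per pathway, one private vector
#' per protein) is drawn by thresholding a Brownian trait on the tree, with
#' per-genome marginal presence probabilities `q` (a smooth tree trait
#' clamped to `[0.2, 0.8]` so no genome shares nearly all query orthologs
#' by chance and dereplication at 0.9 overlap only collapses genuinely
#' near-identical genomes).  A pathway member takes each entry from its
#' pathway's base vector with probability `co_inheritance` and from its
#' private vector otherwise, then every entry is flipped with
#' `profile_flip_rate` noise; at `co_inheritance = 0` members are fully
#' independent of the pathway.  Profiles with fewer than 3 present genomes
#' are topped up so every protein supports a distance matrix.  Bit scores
#' decay with the genome's tree distance from the query lineage (first
#' tip) around a per-protein self score.
#'
#' Uses the current RNG state (seed once per world).
#'
#' @param config a [world_config()]
#' @param tree tree from [simulate_species_tree()]
#' @return list with `presence` (proteins x genomes 0/1 matrix), `bit`
#'   (bit-score matrix, 0 where absent), `self_bit` (named vector)
#' @export
simulate_presence_profiles <- function(config, tree) {
  stopifnot(inherits(config, "world_config"))
  ann <- pathway_layout(config)
  genomes <- sort(tree$tip.label)
  ng <- length(genomes)
  prots <- sprintf("P%04d", seq_len(config$n_proteins))
  trait <- ape::rTraitCont(tree, model = "BM", sigma = 1.5)[genomes]
  q <- pmin(pmax(stats::plogis(trait), 0.2), 0.8)
  # tree-correlated standard-normal deviates: rows ~ MVN(0, vcv(tree)),
  # scaled to unit marginal variance, thresholded at qnorm(q)
  C <- ape::vcv(tree)[genomes, genomes]
  Lt <- chol(C + diag(1e-9, ng))
  zsd <- sqrt(diag(C))
  pw_ids <- unique(ann$level3)
  ndraw <- length(pw_ids) + length(prots)
  Z <- matrix(stats::rnorm(ndraw * ng), ndraw, ng) %*% Lt
  Z <- sweep(Z, 2L, zsd, "/")
  thresh <- stats::qnorm(q)
  V <- sweep(Z, 2L, thresh, "<") * 1L  # each row: one presence vector
  base <- V[seq_along(pw_ids), , drop = FALSE]
  rownames(base) <- pw_ids
  own <- V[length(pw_ids) + seq_along(prots), , drop = FALSE]
  rownames(own) <- prots
  presence <- matrix(0L, length(prots), ng, dimnames = list(prots, genomes))
  pw_of <- stats::setNames(ann$level3, ann$protein_id)
  for (p in prots) {
    pw <- pw_of[p]
    v <- if (!is.na(pw)) {
      keep <- stats::runif(ng) < config$co_inheritance
      ifelse(keep, base[pw, ], own[p, ])
    } else own[p, ]
    flip <- stats::runif(ng) < config$profile_flip_rate
    v <- as.integer(ifelse(flip, 1L - v, v))
    if (sum(v) < 3L) v[sample.int(ng, 3L)] <- 1L
    presence[p, ] <- v
  }
  # every genome needs at least one protein (positive protein count)
  empty <- colSums(presence) == 0L
  if (any(empty)) presence[sample.int(length(prots), 1L), empty] <- 1L
  d_ts <- tree_distances(tree)[, genomes[1L]][genomes]
  self_bit <- stats::setNames(stats::runif(length(prots), 400, 1500), prots)
  jitter <- matrix(stats::runif(length(presence), 0.9, 1.1), nrow(presence))
  bit <- presence * outer(self_bit, 1 - 0.6 * d_ts) * jitter
  list(presence = presence, bit = bit, self_bit = self_bit)
}

# ortholog gene id used consistently by the map and the genome tables
synthetic_gene_id <- function(protein, genome) paste(protein, genome, sep = "@")

#' Simulate circular gene orders
#'
#' For each genome, the genes of co-present pathway members form a single
#' co-directional block with intergenic gaps Uniform(0,100) nt with
#' probability `operon_prob`; all other genes are placed as independent
#' singletons with random strand.  Blocks are shuffled and laid around the
#' circle with inter-block gaps Uniform(150,5000) nt, so genes from
#' different blocks can never satisfy the 100-nt cluster rule.
#'
#' @param config a [world_config()]
#' @param presence 0/1 proteins x genomes matrix
#' @return named list of [genome_table()] objects
#' @export
simulate_gene_orders <- function(config, presence) {
  stopifnot(inherits(config, "world_config"))
  ann <- pathway_layout(config)
  members <- split(ann$protein_id, ann$level3)
  genomes <- colnames(presence)
  out <- vector("list", length(genomes))
  names(out) <- genomes
  for (g in genomes) {
    present <- rownames(presence)[presence[, g] == 1L]
    blocks <- list()
    single <- present
    for (pw in names(members)) {
      mem <- intersect(members[[pw]], present)
      if (length(mem) >= 2L && stats::runif(1) < config$operon_prob) {
        blocks[[length(blocks) + 1L]] <- sample(mem)
        single <- setdiff(single, mem)
      }
    }
    for (p in single) blocks[[length(blocks) + 1L]] <- p
    blocks <- blocks[sample.int(length(blocks))]
    gene <- unlist(blocks, use.names = FALSE)
    nb <- lengths(blocks)
    bidx <- rep(seq_along(blocks), nb)
    first_of_block <- !duplicated(bidx)
    gaps_before <- ifelse(first_of_block,
                          round(stats::runif(length(gene), 150, 5000)),
                          round(stats::runif(length(gene), 0, 100)))
    lens <- round(stats::runif(length(gene), 300, 3000))
    starts <- cumsum(gaps_before) + c(0, cumsum(lens)[-length(gene)]) + 1
    ends <- starts + lens - 1
    block_strand <- vapply(blocks, function(b) sample(c("+", "-"), 1L),
                           character(1))
    strand <- rep(block_strand, nb)
    out[[g]] <- genome_table(
      g, max(ends) + round(stats::runif(1, 150, 5000)),
      data.frame(gene_id = synthetic_gene_id(gene, g), start = starts,
                 end = ends, strand = strand, stringsAsFactors = FALSE))
  }
  out
}

#' Simulate an expression compendium
#'
#' Each pathway carries a latent condition program; a member gene's profile
#' is `coexpression * pathway program + (1 - coexpression) * own program +
#' Normal(0, expr_sigma)` noise.  Unannotated genes follow only their own
#' program.  Columns are scaled by a log-normal per-condition factor so
#' conditions differ in variance (exercising condition selection) without
#' altering which genes correlate.
#'
#' @param config a [world_config()]
#' @return numeric genes x conditions matrix
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "world_config"))
  ann <- pathway_layout(config)
  prots <- sprintf("P%04d", seq_len(config$n_proteins))
  conds <- sprintf("cond%03d", seq_len(config$n_conditions))
  pw_of <- stats::setNames(ann$level3, ann$protein_id)
  latent <- list()
  for (pw in unique(ann$level3)) latent[[pw]] <- stats::rnorm(config$n_conditions)
  w <- config$coexpression
  X <- matrix(0, length(prots), length(conds), dimnames = list(prots, conds))
  for (p in prots) {
    own <- stats::rnorm(config$n_conditions)
    pw <- pw_of[p]
    sig <- if (!is.na(pw)) w * latent[[pw]] + (1 - w) * own else own
    X[p, ] <- sig + stats::rnorm(config$n_conditions, sd = config$expr_sigma)
  }
  scale_c <- exp(stats::rnorm(config$n_conditions, sd = 0.4))
  sweep(X, 2L, scale_c, "*")
}

#' Simulate per-protein distance matrices and genome shared-ortholog counts
#'
#' A protein's raw matrix over the genomes where it is present is
#' `rate * tree distance + coevolution * R + Normal(0, dist_sigma)` with a
#' modest per-protein rate (Uniform(0.8, 1.2)) and, for pathway members, a
#' shared symmetric residual `R` (entries Uniform(0, 0.5)) common to the
#' whole pathway - the co-evolution signal the mirrortree correction is
#' meant to expose.  Entries are floored at 0; the diagonal is 0.  Shared
#' ortholog counts per genome pair are derived from the presence matrix.
#'
#' @param config a [world_config()]
#' @param tree species tree
#' @param presence 0/1 proteins x genomes matrix
#' @return list with `matrices` (named list of [distance_matrix()]) and
#'   `shared` (data.frame `genome_a`, `genome_b`, `shared`)
#' @export
simulate_distance_matrices <- function(config, tree, presence) {
  stopifnot(inherits(config, "world_config"))
  ann <- pathway_layout(config)
  Dt <- tree_distances(tree)
  genomes <- colnames(presence)
  Dt <- Dt[genomes, genomes]
  ng <- length(genomes)
  pw_of <- stats::setNames(ann$level3, ann$protein_id)
  sym_mat <- function(gen) {
    m <- matrix(0, ng, ng, dimnames = list(genomes, genomes))
    m[upper.tri(m)] <- gen(sum(upper.tri(m)))
    m + t(m)
  }
  R <- list()
  for (pw in unique(ann$level3)) {
    R[[pw]] <- sym_mat(function(n) stats::runif(n, 0, 0.5))
  }
  prots <- rownames(presence)
  rate <- stats::setNames(stats::runif(length(prots), 0.8, 1.2), prots)
  matrices <- vector("list", length(prots))
  names(matrices) <- prots
  for (p in prots) {
    sp <- genomes[presence[p, ] == 1L]
    M <- rate[p] * Dt[sp, sp, drop = FALSE]
    pw <- pw_of[p]
    if (!is.na(pw)) M <- M + config$coevolution * R[[pw]][sp, sp, drop = FALSE]
    noise <- sym_mat(function(n) stats::rnorm(n, sd = config$dist_sigma))
    M <- M + noise[sp, sp, drop = FALSE]
    M <- pmax(M, 0)
    diag(M) <- 0
    matrices[[p]] <- distance_matrix(M, p)
  }
  S <- crossprod(presence)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  shared <- data.frame(genome_a = genomes[idx[, 1L]],
                       genome_b = genomes[idx[, 2L]],
                       shared = as.integer(S[idx]), stringsAsFactors = FALSE)
  list(matrices = matrices, shared = shared)
}

#' Simulate a complete synthetic world
#'
#' Runs all generators under `config$seed` and packages their outputs with
#' the ground-truth linkage labels (pairs sharing a level-3 pathway, i.e.
#' the positives of [build_global_gold()] on the emitted annotation).
#'
#' @param config a [world_config()]
#' @return object of class `synthetic_world`: list with `config`, `tree`,
#'   `annotation`, `genomes`, `ortholog_map`, `expression`,
#'   `dist_matrices`, `genome_shared`, `truth_pairs`
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  tree <- simulate_species_tree(config$n_genomes, config$seed)
  ann <- pathway_layout(config)
  prof <- simulate_presence_profiles(config, tree)
  genomes <- simulate_gene_orders(config, prof$presence)
  expression <- simulate_expression(config)
  dm <- simulate_distance_matrices(config, tree, prof$presence)
  idx <- which(prof$presence == 1L, arr.ind = TRUE)
  prots <- rownames(prof$presence); gids <- colnames(prof$presence)
  entries <- data.frame(
    query_id = prots[idx[, 1L]],
    genome_id = gids[idx[, 2L]],
    ortholog_gene_id = synthetic_gene_id(prots[idx[, 1L]], gids[idx[, 2L]]),
    bit_score = prof$bit[idx],
    self_bit_score = prof$self_bit[idx[, 1L]],
    stringsAsFactors = FALSE)
  omap <- ortholog_map(entries, colSums(prof$presence))
  gold <- build_global_gold(ann)
  truth <- do.call(rbind, strsplit(gold$positives, "\x1f", fixed = TRUE))
  truth_pairs <- data.frame(protein_a = truth[, 1L], protein_b = truth[, 2L],
                            stringsAsFactors = FALSE)
  structure(list(config = config, tree = tree, annotation = ann,
                 genomes = genomes, ortholog_map = omap,
                 expression = expression, dist_matrices = dm$matrices,
                 genome_shared = dm$shared, truth_pairs = truth_pairs),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d genomes, %d proteins, %d truth pairs (seed %d)\n",
              length(x$genomes), x$config$n_proteins, nrow(x$truth_pairs),
              x$config$seed))
  invisible(x)
}

#' Export a synthetic world to a directory of TSV files
#'
#' Writes every input the pipeline consumes (`genomes/*.tsv`,
#' `orthologs.tsv`, `genome_counts.tsv`, `expression.tsv`,
#' `annotations.tsv`, `dist_matrices/*.tsv`, `genome_shared_counts.tsv`)
#' plus `truth_pairs.tsv` and `world_config.yaml`.  Every file header
#' carries the configuration hash and seed; numeric values are printed with
#' `%.17g` so [import_world()] reproduces the world exactly.
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
export_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dist_matrices"), showWarnings = FALSE)
  cmt <- c(sprintf("config_hash=%s", world$config$hash),
           sprintf("seed=%d", world$config$seed))
  for (g in names(world$genomes)) {
    write_genome_table(world$genomes[[g]],
                       file.path(dir, "genomes", paste0(g, ".tsv")), cmt)
  }
  write_ortholog_map(world$ortholog_map, file.path(dir, "orthologs.tsv"),
                     file.path(dir, "genome_counts.tsv"), cmt)
  write_expression_matrix(world$expression, file.path(dir, "expression.tsv"),
                          cmt)
  write_pathway_annotations(world$annotation,
                            file.path(dir, "annotations.tsv"), cmt)
  for (p in names(world$dist_matrices)) {
    write_distance_matrix(world$dist_matrices[[p]],
                          file.path(dir, "dist_matrices", paste0(p, ".tsv")),
                          cmt)
  }
  con <- file(file.path(dir, "genome_shared_counts.tsv"), "w")
  writeLines(c(paste0("# ", cmt), "genome_a\tgenome_b\tshared",
               sprintf("%s\t%s\t%d", world$genome_shared$genome_a,
                       world$genome_shared$genome_b,
                       world$genome_shared$shared)), con)
  close(con)
  con <- file(file.path(dir, "truth_pairs.tsv"), "w")
  writeLines(c(paste0("# ", cmt), "protein_a\tprotein_b",
               sprintf("%s\t%s", world$truth_pairs$protein_a,
                       world$truth_pairs$protein_b)), con)
  close(con)
  write_world_config(world$config, file.path(dir, "world_config.yaml"))
  invisible(dir)
}

# Flat YAML (scalars only).  The r-yaml package is not available in the
# target environment, and this config is a flat key:value mapping, so a
# minimal emitter/parser is used.
write_world_config <- function(config, path) {
  keys <- setdiff(names(config), "hash")
  num <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.integer(v)) sprintf("%d", v) else sprintf("%.17g", v)
  }, character(1))
  writeLines(c("# synthetic world configuration",
               sprintf("config_hash: %s", config$hash),
               sprintf("%s: %s", keys, num)), path)
  invisible(path)
}

read_world_config <- function(path) {
  assert_file_exists(path, "read_world_config")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  get <- function(k) vals[match(k, keys)]
  world_config(
    n_genomes = as.integer(get("n_genomes")),
    n_proteins = as.integer(get("n_proteins")),
    n_categories = as.integer(get("n_categories")),
    pathways_per_category = as.integer(get("pathways_per_category")),
    proteins_per_pathway = as.integer(get("proteins_per_pathway")),
    n_conditions = as.integer(get("n_conditions")),
    co_inheritance = as.numeric(get("co_inheritance")),
    operon_prob = as.numeric(get("operon_prob")),
    coexpression = as.numeric(get("coexpression")),
    coevolution = as.numeric(get("coevolution")),
    profile_flip_rate = as.numeric(get("profile_flip_rate")),
    expr_sigma = as.numeric(get("expr_sigma")),
    dist_sigma = as.numeric(get("dist_sigma")),
    seed = as.integer(get("seed")))
}

#' Import a synthetic world exported by [export_world()]
#'
#' Re-reads every file through the standard readers, so the import also
#' validates that the exported files satisfy all type invariants.  The
#' species tree itself is not serialized (it only seeds the generators);
#' the returned world carries `tree = NULL`.
#'
#' @param dir directory written by [export_world()]
#' @return a `synthetic_world`
#' @export
import_world <- function(dir) {
  config <- read_world_config(file.path(dir, "world_config.yaml"))
  gfiles <- sort(list.files(file.path(dir, "genomes"), full.names = TRUE))
  if (!length(gfiles)) stop("import_world: no genome tables found",
                            call. = FALSE)
  genomes <- lapply(gfiles, read_genome_table)
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  omap <- read_ortholog_map(file.path(dir, "orthologs.tsv"),
                            file.path(dir, "genome_counts.tsv"))
  expression <- read_expression_matrix(file.path(dir, "expression.tsv"))
  ann <- read_pathway_annotations(file.path(dir, "annotations.tsv"))
  dfiles <- sort(list.files(file.path(dir, "dist_matrices"),
                            full.names = TRUE))
  dmats <- lapply(dfiles, read_distance_matrix)
  names(dmats) <- vapply(dmats, attr, "", "label")
  shared <- read_tsv_plain(file.path(dir, "genome_shared_counts.tsv"))
  truth <- read_tsv_plain(file.path(dir, "truth_pairs.tsv"))
  structure(list(config = config, tree = NULL, annotation = ann,
                 genomes = genomes, ortholog_map = omap,
                 expression = expression, dist_matrices = dmats,
                 genome_shared = shared, truth_pairs = truth),
            class = "synthetic_world")
}
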