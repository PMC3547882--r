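# Fixture builders shared by the unit tests.  Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

options(linkmark.log_level = "quiet")

# genome table from gene lengths and gaps laid head-to-tail
toy_genome <- function(id, lens, gaps_before, strands,
                       tail_gap = 500L) {
  starts <- cumsum(gaps_before) + c(0, cumsum(lens)[-length(lens)]) + 1
  ends <- starts + lens - 1
  genome_table(id, max(ends) + tail_gap,
               data.frame(gene_id = sprintf("%s_g%02d", id, seq_along(lens)),
                          start = starts, end = ends, strand = strands,
                          stringsAsFactors = FALSE))
}

# ortholog map in which `placement[[genome]]` names, per query protein, the
# gene id of its ortholog in that genome (NA/absent = no ortholog)
toy_omap <- function(placement, bit = 100, self_bit = 200,
                     counts = NULL) {
  rows <- list()
  for (g in names(placement)) {
    pl <- placement[[g]]
    pl <- pl[!is.na(pl)]
    if (!length(pl)) next
    rows[[g]] <- data.frame(query_id = names(pl), genome_id = g,
                            ortholog_gene_id = unname(pl), bit_score = bit,
                            self_bit_score = self_bit,
                            stringsAsFactors = FALSE)
  }
  counts <- counts %||% stats::setNames(rep(100L, length(placement)),
                                        names(placement))
  ortholog_map(do.call(rbind, rows), counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The operon worked example: four reference genomes, query proteins C and D;
# their orthologs sit in the same co-directional cluster in three genomes
# and far apart in the fourth.
fig_gc_world <- function() {
  genomes <- list(
    # C and D adjacent, same strand, gap 50 (co-clustered)
    g1 = toy_genome("g1", lens = c(900, 900, 900), gaps_before = c(200, 50, 400),
                    strands = c("+", "+", "-")),
    g2 = toy_genome("g2", lens = c(600, 600, 600), gaps_before = c(300, 80, 500),
                    strands = c("-", "-", "+")),
    g3 = toy_genome("g3", lens = c(500, 500, 500), gaps_before = c(150, 100, 900),
                    strands = c("+", "+", "+")),
    # C and D separated by a large gap: not co-clustered
    g4 = toy_genome("g4", lens = c(700, 700, 700), gaps_before = c(250, 4000, 600),
                    strands = c("+", "+", "-")))
  placement <- list(
    g1 = c(C = "g1_g01", D = "g1_g02"),
    g2 = c(C = "g2_g01", D = "g2_g02"),
    g3 = c(C = "g3_g02", D = "g3_g01"),
    g4 = c(C = "g4_g01", D = "g4_g02"))
  list(genomes = genomes, omap = toy_omap(placement))
}

# small synthetic world config for property-style tests (fast: ~0.3 s per
# world); counts chosen so the pair universe is still in the thousands
small_world_config <- function(seed, ...) {
  world_config(n_genomes = 25L, n_proteins = 56L, n_categories = 3L,
               pathways_per_category = 2L, proteins_per_pathway = 8L,
               n_conditions = 100L, seed = seed, ...)
}

# mean score of truth pairs vs non-truth pairs for one score table
linked_vs_unlinked <- function(tab, world) {
  truth_keys <- linkmark:::pair_key(world$truth_pairs$protein_a,
                                    world$truth_pairs$protein_b)
  keys <- linkmark:::pair_key(tab$protein_a, tab$protein_b)
  linked <- keys %in% truth_keys
  c(linked = mean(tab$score[linked]), unlinked = mean(tab$score[!linked]))
}

# AUC of one method against the world's global truth
world_auc <- function(world, method, ...) {
  tab <- score_world(world, method, ...)[[method]]
  roc_curve(tab, build_global_gold(world$annotation))$auc
}

# random pair score table over a random protein set
random_score_table <- function(n = 10L, method = "PP") {
  prots <- sprintf("X%02d", seq_len(n + 1L))
  pr <- all_pairs(prots)
  keep <- sample(nrow(pr), n)
  pair_score_table(pr$protein_a[keep], pr$protein_b[keep],
                   round(stats::runif(n), 3),
                   undefined = stats::runif(n) < 0.2, method = method,
                   seed = 7L, config_hash = "deadbeef")
}
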