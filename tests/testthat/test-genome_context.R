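test_that("gene_rank_distance matches the walk-both-arcs oracle", {
  expect_identical(gene_rank_distance(2L, 5L, 10L), 3L)
  expect_identical(gene_rank_distance(0L, 9L, 10L), 1L)
  expect_identical(gene_rank_distance(0L, 5L, 10L), 5L)
  for (G in c(2L, 3L, 7L, 12L, 30L)) {
    for (a in 0:(G - 1L)) for (b in 0:(G - 1L)) {
      if (a == b) next
      d <- gene_rank_distance(a, b, G)
      expect_identical(d, oracle_circ_dist(a, b, G))
      expect_identical(d, gene_rank_distance(b, a, G))  # symmetry
      expect_true(d >= 1L && d <= G %/% 2L)
    }
  }
  expect_error(gene_rank_distance(3L, 3L, 10L), "equal ranks")
  expect_error(gene_rank_distance(10L, 2L, 10L), "\\[0, G\\)")
})

make_rank_genome <- function(id, n, strands = rep("+", n)) {
  toy_genome(id, lens = rep(500L, n), gaps_before = rep(1000L, n),
             strands = strands)
}

test_that("gn_scores takes the best genome and normalizes by floor(G/2)", {
  # adjacent ranks in a 1000-gene genome, antipodal in a 10-gene genome
  g_big <- make_rank_genome("big", 1000L)
  g_small <- make_rank_genome("small", 10L)
  omap <- toy_omap(list(
    big = c(A = "big_g0001", B = "big_g0002"),
    small = c(A = "small_g01", B = "small_g06")))
  # toy_genome ids use %02d; the big genome needs 4 digits
  omap$entries$ortholog_gene_id[1:2] <- g_big$genes$gene_id[1:2]
  tab <- gn_scores(data.frame(a = "A", b = "B"), omap,
                   list(g_big, g_small))
  expect_equal(tab$score, 1 - 1 / 500)  # 0.998 from the adjacent pair
  expect_false(tab$undefined)

  # orthologs antipodal in the only shared genome -> 1 - 1 = 0
  omap2 <- toy_omap(list(small = c(A = "small_g01", B = "small_g06")))
  tab2 <- gn_scores(data.frame(a = "A", b = "B"), omap2, list(g_small))
  expect_equal(tab2$score, 0)
  expect_false(tab2$undefined)

  # never co-present -> undefined with score 0
  omap3 <- toy_omap(list(small = c(A = "small_g01"),
                         big = c(B = "big_g01")))
  omap3$entries$ortholog_gene_id[2] <- g_big$genes$gene_id[1]
  tab3 <- gn_scores(data.frame(a = "A", b = "B"), omap3,
                    list(g_big, g_small))
  expect_equal(tab3$score, 0)
  expect_true(tab3$undefined)

  # unknown ortholog gene id is a hard error naming genome and gene
  omap4 <- toy_omap(list(small = c(A = "nope", B = "small_g02")))
  expect_error(gn_scores(data.frame(a = "A", b = "B"), omap4, list(g_small)),
               "'nope' not found in genome table 'small'")
})

test_that("gn score is monotone as one genome's pair distance shrinks", {
  g10 <- make_rank_genome("m", 20L)
  score_at <- function(rank_b) {
    omap <- toy_omap(list(m = c(A = g10$genes$gene_id[1],
                                B = g10$genes$gene_id[rank_b + 1L])))
    gn_scores(data.frame(a = "A", b = "B"), omap, list(g10))$score
  }
  s <- vapply(c(10L, 7L, 4L, 2L, 1L), score_at, numeric(1))
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("detect_gene_clusters honors gap cutoff, strand, and circularity", {
  # gaps 50 and 100 (inclusive boundary): one cluster of 3
  g <- toy_genome("a", lens = c(300, 300, 300), gaps_before = c(5000, 50, 100),
                  strands = c("+", "+", "+"), tail_gap = 5000L)
  cl <- detect_gene_clusters(g, 100L)
  expect_length(cl, 1L)
  expect_identical(cl[[1L]]$members, g$genes$gene_id)

  # gap 101 splits
  g2 <- toy_genome("a", lens = c(300, 300, 300), gaps_before = c(5000, 50, 101),
                   strands = c("+", "+", "+"), tail_gap = 5000L)
  cl2 <- detect_gene_clusters(g2, 100L)
  expect_length(cl2, 2L)
  expect_identical(sort(lengths(lapply(cl2, `[[`, "members"))), c(1L, 2L))

  # strand break regardless of gap
  g3 <- toy_genome("a", lens = c(300, 300, 300), gaps_before = c(5000, 10, 10),
                   strands = c("+", "+", "-"), tail_gap = 5000L)
  expect_length(detect_gene_clusters(g3, 100L), 2L)

  # overlapping genes count as gap 0
  g4 <- genome_table("a", 10000L, data.frame(
    gene_id = c("x", "y"), start = c(100L, 350L), end = c(400L, 700L),
    strand = c("-", "-")))
  expect_length(detect_gene_clusters(g4, 100L), 1L)

  # circular wrap-around: last and first gene co-directional, 60 nt apart
  # across the origin
  g5 <- toy_genome("a", lens = c(300, 300, 300), gaps_before = c(30, 2000, 2000),
                   strands = c("+", "-", "+"), tail_gap = 30L)
  cl5 <- detect_gene_clusters(g5, 100L)
  expect_length(cl5, 2L)
  wrapped <- cl5[[which(vapply(cl5, function(x) length(x$members), 1L) == 2L)]]
  expect_identical(wrapped$members, c("a_g03", "a_g01"))  # walk order
})

test_that("clusters partition the gene set and match the adjacency oracle", {
  withr::local_seed(7)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    g <- toy_genome("r", lens = sample(200:1000, n, replace = TRUE),
                    gaps_before = sample(c(0:120, 150:400), n, replace = TRUE),
                    strands = sample(c("+", "-"), n, replace = TRUE),
                    tail_gap = sample(c(10L, 300L), 1))
    cl <- detect_gene_clusters(g, 100L)
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members, g$genes$gene_id)       # partition: coverage
    expect_identical(anyDuplicated(members), 0L)    # partition: disjoint
    oracle <- oracle_clusters(g, 100L)
    expect_identical(length(cl), length(oracle))
    got <- lapply(cl, function(x) sort(x$members))
    want <- lapply(oracle, sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("cluster partition is invariant to rotating the circle origin", {
  g <- toy_genome("rot", lens = rep(400L, 5),
                  gaps_before = c(40L, 60L, 300L, 20L, 90L), tail_gap = 35L,
                  strands = c("+", "+", "-", "-", "-"))
  part <- function(gt) {
    cl <- detect_gene_clusters(gt, 100L)
    sort(vapply(cl, function(x) paste(sort(x$members), collapse = ","), ""))
  }
  base <- part(g)
  # new origin inside the 300-nt gap before gene 3
  delta <- g$genes$start[3L] - 10L
  rot <- function(pos) ((pos - delta) %% g$length_bp) + 1L
  g_rot <- genome_table("rot", g$length_bp, data.frame(
    gene_id = g$genes$gene_id, start = rot(g$genes$start - 1L),
    end = rot(g$genes$end - 1L), strand = g$genes$strand))
  expect_identical(part(g_rot), base)
})

test_that("gc_scores reproduces the co-clustered-in-3-of-4 worked example", {
  w <- fig_gc_world()
  tab <- gc_scores(data.frame(a = "C", b = "D"), w$omap, w$genomes)
  expect_equal(tab$score, 3 / 4)
  expect_false(tab$undefined)

  # co-clustered wherever co-present -> 1
  tab1 <- gc_scores(data.frame(a = "C", b = "D"), w$omap, w$genomes[1:3])
  expect_equal(tab1$score, 1)

  # co-present but never co-clustered -> 0
  tab0 <- gc_scores(data.frame(a = "C", b = "D"), w$omap, w$genomes[4])
  expect_equal(tab0$score, 0)
  expect_false(tab0$undefined)

  # never co-present -> undefined
  omap_np <- toy_omap(list(g1 = c(C = "g1_g01"), g4 = c(D = "g4_g02")))
  tabu <- gc_scores(data.frame(a = "C", b = "D"), omap_np,
                    w$genomes[c(1, 4)])
  expect_true(tabu$undefined)
  expect_equal(tabu$score, 0)
})

test_that("gc_scores equals a brute-force genome count on random worlds", {
  withr::local_seed(31)
  for (rep in 1:5) {
    ngen <- sample(2:6, 1)
    nprot <- 6L
    prots <- sprintf("Q%d", seq_len(nprot))
    genomes <- list(); placement <- list()
    for (gi in seq_len(ngen)) {
      id <- sprintf("w%d", gi)
      n <- sample(4:9, 1)
      genomes[[id]] <- toy_genome(
        id, lens = sample(200:900, n, replace = TRUE),
        gaps_before = sample(c(0:120, 200:900), n, replace = TRUE),
        strands = sample(c("+", "-"), n, replace = TRUE))
      pres <- sample(prots, min(n, sample(2:nprot, 1)))
      placement[[id]] <- stats::setNames(
        genomes[[id]]$genes$gene_id[seq_along(pres)], pres)
    }
    omap <- toy_omap(placement)
    pairs <- all_pairs(prots)
    tab <- gc_scores(pairs, omap, genomes, max_gap = 100L)
    # brute force via the independent adjacency-component oracle
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$protein_a[k]; b <- pairs$protein_b[k]
      nb <- 0L; ns <- 0L
      for (id in names(genomes)) {
        pl <- placement[[id]]
        if (!(a %in% names(pl)) || !(b %in% names(pl))) next
        nb <- nb + 1L
        comp <- oracle_clusters(genomes[[id]], 100L)
        same <- any(vapply(comp, function(m) all(c(pl[[a]], pl[[b]]) %in% m),
                           logical(1)))
        ns <- ns + same
      }
      expected <- if (nb == 0L) 0 else ns / nb
      expect_equal(tab$score[tab$protein_a == min(a, b) &
                               tab$protein_b == max(a, b)], expected)
    }
  }
})
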