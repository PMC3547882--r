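dm_from <- function(m, ids, label = "pX", allow_negative = FALSE) {
  dimnames(m) <- list(ids, ids)
  distance_matrix(m, label, allow_negative = allow_negative)
}

rand_dm <- function(ids, label = "pX", scale = 1) {
  n <- length(ids)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(sum(upper.tri(m)), 0, scale)
  dm_from(m + t(m), ids, label)
}

test_that("p-distances count mismatches over mutually non-gap columns", {
  expect_equal(unname(distance_matrix_from_alignment(
    c(s1 = "ACDE", s2 = "ACDE"))["s1", "s2"]), 0)
  expect_equal(unname(distance_matrix_from_alignment(
    c(s1 = "AAAA", s2 = "TTTT"))["s1", "s2"]), 1)
  expect_equal(unname(distance_matrix_from_alignment(
    c(s1 = "ACDE", s2 = "ACDF"))["s1", "s2"]), 0.25)
  # gaps excluded from the comparable-column count
  d <- distance_matrix_from_alignment(c(s1 = "AC-EF", s2 = "ACD-F",
                                        s3 = "ACDEF"))
  expect_equal(unname(d["s1", "s2"]), 0)    # 3 comparable columns, all equal
  expect_equal(unname(d["s1", "s3"]), 0)
  expect_error(distance_matrix_from_alignment(c(s1 = "AC", s2 = "ACD")),
               "lengths differ")
  expect_error(distance_matrix_from_alignment(c(s1 = "AC", s1 = "AG")),
               "duplicate species")
  expect_error(distance_matrix_from_alignment(c(s1 = "A-", s2 = "-A")),
               "no comparable columns")
})

test_that("genome_distance follows 1 - shared/min with bounds checks", {
  expect_equal(genome_distance(7, 7, 7), 0)
  expect_equal(genome_distance(4, 9, 0), 1)
  expect_equal(genome_distance(4, 6, 2), 0.5)
  expect_error(genome_distance(4, 6, 5), "exceeds min")
})

test_that("build_genome_distance_matrix fills DG element-wise", {
  om <- ortholog_map(data.frame(query_id = "p", genome_id = "A",
                                ortholog_gene_id = "x", bit_score = 60,
                                self_bit_score = 100),
                     c(A = 4L, B = 6L, C = 8L))
  shared <- data.frame(genome_a = c("A", "A", "B"),
                       genome_b = c("B", "C", "C"), shared = c(2L, 4L, 6L))
  dg <- build_genome_distance_matrix(om, shared)
  expect_equal(unclass(dg), rbind(c(0, .5, 0), c(.5, 0, 0), c(0, 0, 0)),
               ignore_attr = TRUE)
  # identical genomes -> 0; disjoint -> 1
  dg2 <- build_genome_distance_matrix(
    om, data.frame(genome_a = "A", genome_b = "B", shared = 4L),
    genome_ids = c("A", "B"))
  expect_equal(unname(dg2["A", "B"]), 0)
  expect_error(build_genome_distance_matrix(
    om, data.frame(genome_a = "A", genome_b = "B", shared = 1L),
    genome_ids = c("A", "B", "C")), "missing shared count for A/C")
})

test_that("compute_rescale_factor is the max PCC against DG", {
  withr::local_seed(13)
  ids <- sprintf("s%d", 1:6)
  dg <- rand_dm(ids, "GENOME")
  # a matrix exactly equal to DG gives rho = 1 regardless of scaling
  exact <- dm_from(unclass(dg) * 2, ids, "pA")
  noisy <- dm_from(pmax(unclass(dg) * 0.5 +
                          rand_dm(ids, scale = 0.2), 0), ids, "pB")
  diag(noisy) <- 0
  rs <- compute_rescale_factor(dg, list(pA = exact, pB = noisy))
  expect_equal(rs$rho, 1)
  expect_identical(rs$argmax_protein, "pA")

  # brute-force oracle over hand-built matrices
  mats <- list(pA = rand_dm(ids, "pA"), pB = rand_dm(ids, "pB"),
               pC = rand_dm(ids[1:4], "pC"))
  rs2 <- compute_rescale_factor(dg, mats)
  byhand <- vapply(mats, function(m) {
    common <- intersect(rownames(m), rownames(dg))
    a <- m[common, common]; b <- unclass(dg)[common, common]
    oracle_pcc(a[upper.tri(a)], b[upper.tri(b)])
  }, numeric(1))
  expect_equal(rs2$rho, max(byhand))
  expect_identical(rs2$argmax_protein, names(which.max(byhand)))

  expect_error(compute_rescale_factor(dg, list(pZ = rand_dm(ids[1:2]))),
               "no protein matrix shares")
  anti <- max(dg) - unclass(dg)
  diag(anti) <- 0
  expect_error(compute_rescale_factor(dg, list(pN = dm_from(anti, ids, "pN"))),
               "non-positive")
})

test_that("correct_distance_matrix subtracts the rescaled matrix from DG", {
  withr::local_seed(17)
  ids <- sprintf("s%d", 1:4)
  dg <- rand_dm(ids, "GENOME")
  rho <- 0.6
  dx <- dm_from(unclass(dg) * rho, ids, "pA")
  corr <- correct_distance_matrix(dx, dg, list(rho = rho))
  expect_equal(max(abs(corr)), 0)  # exact cancellation

  # rho = 1 and DX = DG + C off-diagonal -> corrected == -C off-diagonal
  C <- 0.25
  off <- matrix(C, 4, 4); diag(off) <- 0
  dx2 <- dm_from(unclass(dg) + off, ids, "pB")
  corr2 <- correct_distance_matrix(dx2, dg, list(rho = 1))
  expect_equal(unname(corr2[upper.tri(corr2)]), rep(-C, 6))
  expect_equal(unname(diag(corr2)), rep(0, 4))

  # random fixture equals element-wise hand computation on common species
  dx3 <- rand_dm(ids[1:3], "pC")
  corr3 <- correct_distance_matrix(dx3, dg, list(rho = 0.8))
  want <- unclass(dg)[ids[1:3], ids[1:3]] - unclass(dx3) / 0.8
  diag(want) <- 0
  expect_equal(unclass(corr3), want)

  expect_error(correct_distance_matrix(rand_dm(ids[1:2], "pD"), dg,
                                       list(rho = 1)), "common species")
})

test_that("gm_scores correlates upper triangles over common species", {
  withr::local_seed(23)
  ids <- sprintf("s%02d", 1:12)
  m1 <- rand_dm(ids, "pA")
  m2 <- dm_from(unclass(m1), ids, "pB")
  tab <- gm_scores(data.frame(a = "pA", b = "pB"),
                   list(pA = m1, pB = m2), min_common_species = 10L)
  expect_equal(tab$score, 1)

  # fewer than min_common_species -> undefined
  m3 <- rand_dm(ids[1:5], "pC")
  tab2 <- gm_scores(data.frame(a = "pA", b = "pC"),
                    list(pA = m1, pC = m3), min_common_species = 10L)
  expect_true(tab2$undefined)
  expect_equal(tab2$score, 0)

  # brute-force definitional PCC on two 12-species matrices sharing 11
  m4 <- rand_dm(ids[1:11], "pD")
  m5 <- rand_dm(ids[2:12], "pE")
  tab3 <- gm_scores(data.frame(a = "pD", b = "pE"),
                    list(pD = m4, pE = m5), min_common_species = 10L)
  common <- ids[2:11]
  a <- m4[common, common]; b <- m5[common, common]
  want <- max(0, oracle_pcc(a[upper.tri(a)], b[upper.tri(b)]))
  expect_equal(tab3$score, want)

  expect_error(gm_scores(data.frame(a = "pA", b = "zz"), list(pA = m1)),
               "no corrected matrix")
})

test_that("gm_scores is invariant under common species relabeling", {
  withr::local_seed(29)
  ids <- sprintf("s%02d", 1:12)
  m1 <- rand_dm(ids, "pA"); m2 <- rand_dm(ids, "pB")
  s1 <- gm_scores(data.frame(a = "pA", b = "pB"), list(pA = m1, pB = m2))
  relabel <- stats::setNames(sprintf("z%02d", sample(12)), ids)
  rl <- function(m) {
    d <- unclass(m)
    dimnames(d) <- list(unname(relabel[rownames(m)]),
                        unname(relabel[colnames(m)]))
    o <- order(rownames(d))
    distance_matrix(d[o, o], attr(m, "label"), allow_negative = TRUE)
  }
  s2 <- gm_scores(data.frame(a = "pA", b = "pB"),
                  list(pA = rl(m1), pB = rl(m2)))
  expect_equal(s1$score, s2$score)
})

test_that("the DG correction strips the shared tree signal", {
  # stated world: DX = TreeDist + noise for unlinked proteins, plus a shared
  # residual R for linked pairs; sigma = 0.05, |R| amplitude = 0.5
  n_sp <- 20L
  res <- t(vapply(1:20, function(s) {
    tree <- simulate_species_tree(n_sp, seed = 900 + s)
    Dt <- ape::cophenetic.phylo(tree)
    Dt <- Dt[sort(rownames(Dt)), sort(colnames(Dt))]
    Dt <- Dt / max(Dt)
    ids <- rownames(Dt)
    dg <- dm_from(Dt, ids, "GENOME")
    sym_noise <- function(sd) {
      m <- matrix(0, n_sp, n_sp)
      m[upper.tri(m)] <- rnorm(sum(upper.tri(m)), sd = sd)
      m + t(m)
    }
    sym_resid <- function() {
      m <- matrix(0, n_sp, n_sp)
      m[upper.tri(m)] <- runif(sum(upper.tri(m)), 0, 0.5)
      m + t(m)
    }
    mk <- function(label, R = 0) {
      m <- pmax(Dt + R + sym_noise(0.05), 0)
      diag(m) <- 0
      dm_from(m, ids, label)
    }
    R <- sym_resid()
    mats <- list(u1 = mk("u1"), u2 = mk("u2"), u3 = mk("u3"),
                 l1 = mk("l1", R), l2 = mk("l2", R))
    rs <- compute_rescale_factor(dg, mats)
    corr <- lapply(mats, correct_distance_matrix, dg = dg, rescale = rs)
    ut_pcc <- function(a, b) oracle_pcc(a[upper.tri(a)], b[upper.tri(b)])
    raw_u <- c(ut_pcc(mats$u1, mats$u2), ut_pcc(mats$u1, mats$u3),
               ut_pcc(mats$u2, mats$u3))
    corr_u <- c(ut_pcc(corr$u1, corr$u2), ut_pcc(corr$u1, corr$u3),
                ut_pcc(corr$u2, corr$u3))
    c(unlinked = mean(corr_u), linked = ut_pcc(corr$l1, corr$l2),
      removed = mean(raw_u > corr_u))
  }, numeric(3)))
  # corrected matrices of unlinked proteins are near-uncorrelated while the
  # linked pair's shared residual survives the correction
  expect_lt(abs(mean(res[, "unlinked"])), 0.15)
  expect_gt(mean(res[, "linked"]), 0.5)
  # the correction lowers the between-matrix correlation for >= 90% of
  # unlinked pairs (its purpose: raw matrices mirror the tree)
  expect_gte(mean(res[, "removed"]), 0.9)
})

test_that("distance matrices round-trip through TSV", {
  withr::local_seed(37)
  dm <- rand_dm(sprintf("s%d", 1:5), "pQ")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, path, comments = "seed=37")
  back <- read_distance_matrix(path)
  expect_equal(unclass(back), unclass(dm))
  expect_identical(attr(back, "label"), "pQ")
})
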