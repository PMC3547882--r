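---
title: "Genome-context prediction of protein functional linkages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-context prediction of protein functional linkages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(linkmark.log_level = "quiet")
library(linkmark)
```

## The problem

Two proteins that work in the same pathway leave correlated traces in
comparative-genomic data: their genes stay near each other on chromosomes,
they are inherited or lost together across species, their sequences
accumulate substitutions in parallel, and they are expressed under the same
conditions. `linkmark` implements five classical scorers that each read one
of these traces for a query proteome against a panel of reference genomes,
plus the machinery to benchmark them against a two-level pathway annotation
with ROC/AUC, and a synthetic-world generator so the whole pipeline can be
exercised and calibrated without any external database.

All five scorers emit an interaction score per unordered protein pair on a
0–1 scale, with 1 the strongest evidence of linkage. Pairs a method cannot
evaluate (orthologs never co-occurring, constant profiles, too few shared
species) are kept in the output flagged `undefined` with score 0, so every
method is always evaluated over the identical pair universe.

## The five scorers

**Gene Neighbor (GN).** For each reference genome containing orthologs of
both proteins, the chromosomal distance between the two encoding genes is
measured in gene ranks on the circular chromosome (shorter arc, orientation
ignored) and normalized by `floor(G/2)`, the largest possible rank
separation on a `G`-gene chromosome. The minimum normalized distance across
genomes is subtracted from one, so conserved proximity in even a single
genome yields a score near 1. Rank distance rather than base pairs makes
the normalization exact and insensitive to gene length; the choice is
recorded in the score-table metadata.

**Gene Cluster (GC).** A gene cluster is a maximal run of co-directional
genes whose consecutive intergenic gaps are at most 100 nt (inclusive;
overlapping genes count as gap 0; the junction across the replication
origin is evaluated because the chromosome is circular). The score is the
fraction of reference genomes, among those containing orthologs of both
proteins, in which the two orthologs lie in one cluster. The denominator is
the number of genomes of co-occurrence, not the full panel: the score is a
co-occurrence probability conditional on both genes being present, which
also reproduces the canonical 3-of-4-genomes worked example as 0.75.

**Phylogenetic Profiling (PP).** The profile matrix `P` holds, per query
protein and reference genome, the alignment bit score against the ortholog
(0 when absent). Because the panel contains clusters of near-identical
genomes that would be counted several times, the panel is first
dereplicated: genomes whose query-ortholog sets overlap by more than 90%
(shared count over the smaller set) are clustered by single linkage and the
genome with the largest ortholog set represents each cluster. `P` is then
normalized in two steps — each nonzero cell divided by the protein's
self-alignment bit score (protein divergence), then each column divided by
the mean of its nonzero entries (species divergence) — and the score is the
Pearson correlation (PCC) of two full profile rows, clamped below at 0.
The two-step normalization is one declared stand-in among several
reasonable readings of "normalize for protein and species divergence"; it
is isolated in `normalize_profile_matrix()` so it can be swapped.

**Genome-distance-corrected Mirrortree (GM).** Each protein carries an
inter-species distance matrix `DX` over the genomes where it has an
ortholog (from an alignment via p-distance, or precomputed). Raw mirrortree
correlates two such matrices, but most of that correlation is the shared
species phylogeny. The correction subtracts it using a genome-distance
matrix `DG` whose entries are `1 - n_shared / min(n_A, n_B)` from
per-genome protein totals and pairwise shared-ortholog counts (the exact
functional form is a declared stand-in for a shared-ortholog genome
distance; it is isolated in `genome_distance()`). Protein matrices and `DG`
live on different scales, so every protein matrix is divided by `rho`, the
highest PCC observed between `DG` and any protein matrix, before the
subtraction `corrected = DG - DX / rho`. Negative corrected entries are
retained — they are differences, not distances; only final pair scores are
clamped. The pair score is the PCC of upper-triangle entries over the
species common to both corrected matrices, requiring at least 10 common
species (PCC over fewer points is noise-dominated; configurable).

Note the rescaling divides by a *correlation*, not a regression slope: it
equalizes scales only when `DX` and `DG` are already commensurate. The
tree-signal-removal test constructs that regime explicitly
(`DX = TreeDist + noise` against `DG = TreeDist`) and verifies that
corrected matrices of unlinked proteins are near-uncorrelated while a
shared residual between linked proteins survives.

**Expression Similarity (ES).** Conditions are ranked by the variance of
their values across genes and the 300 most varying are kept ("most
varying" is read as variance; standard deviation would give the identical
ranking). The score is the PCC of two genes' profiles over the conditions
where both are measured, clamped below at 0, requiring at least 3 jointly
measured conditions.

### Clamping and rankings

Negative correlations are clamped to 0 to honor the 0–1 reporting scale.
Clamping is monotone, so the ROC ordering among retained (positive) scores
is unaffected; the benchmark tests assert AUC invariance under strictly
increasing transforms explicitly.

## Benchmarking

A pair is *positive* when the two proteins share at least one level-3
pathway (the finest annotation level); sharing only a level-2 category is
not enough. The global gold standard takes all pairs of annotated proteins
as its universe. Pathway-stratified gold standards, one per level-2
category, share a single universe — every pair sharing any level-3 pathway
of the selected categories — with positives restricted to the category
under evaluation. Because the universe is category-independent,
positives + negatives is one constant across categories, a structural
property the tests assert.

Thresholding is inclusive (`score >= t` predicts positive). ROC curves
sweep the distinct observed scores descending, one step per tied block, so
the trapezoidal AUC equals the Mann–Whitney U-statistic with ties counted
one half; this equality is tested exhaustively on small fixtures. An AUC
summary matrix (categories × methods with `Average` margins) and a TP/FP
threshold series reproduce the two standard summary artifacts of this kind
of benchmark.

## The synthetic world

`simulate_world()` generates every input the pipeline consumes, plus
ground-truth labels (pairs sharing a level-3 pathway). The default world is
60 genomes and 200 proteins organized as 4 categories × 3 pathways × 16
proteins (the remainder unannotated background), with a 380-condition
expression compendium — large enough for stable AUCs, small enough for
seconds-scale runs. Each signal channel is generated independently so a
scorer's recovery is attributable:

- **co-inheritance → PP.** Every presence vector is drawn by thresholding a
  Brownian trait on a simulated pure-birth species tree, giving
  phylogenetically autocorrelated presence with per-genome marginal
  probabilities clamped to [0.2, 0.8]. A pathway member takes each entry
  from its pathway's base vector with probability `co_inheritance` and from
  its own private tree-correlated vector otherwise, then entries flip with
  rate 0.1. The entry-wise mixture makes the two endpoints exact: at 1,
  members are identical; at 0, members are fully independent of the
  pathway. Bit scores decay with tree distance from the query lineage, so
  profile normalization has realistic structure to remove.
- **operon → GC/GN.** Per genome, a pathway's co-present genes form one
  co-directional block with gaps Uniform(0, 100) nt with probability
  `operon_prob`; all other genes are independent singletons. Blocks are
  shuffled around the circle with inter-block gaps Uniform(150, 5000) nt,
  so cross-block genes can never satisfy the 100-nt rule.
- **co-expression → ES.** Pathway members mix a shared latent condition
  program with weight `coexpression` against a private program, plus
  Gaussian noise (sd 0.5); per-condition log-normal scale factors make
  conditions differ in variance without changing which genes correlate.
- **co-evolution → GM.** A protein's distance matrix is
  `rate × tree distance + coevolution × R + noise` (sd 0.05) restricted to
  its present genomes, with `R` a symmetric residual (entries
  Uniform(0, 0.5)) shared by the whole pathway and a modest per-protein
  rate Uniform(0.8, 1.2). Shared-ortholog counts for `DG` come from the
  presence vectors, so the genome distance genuinely tracks the tree.

Two design points deserve emphasis. First, the phylogenetic autocorrelation
of presence is not cosmetic: if presence were driven only by per-genome
rates, shared-ortholog counts between close and distant genomes would not
differ, `DG` would carry no speciation signal, and the GM rescale factor
could legitimately fail (no protein matrix positively correlated with
`DG`). Second, the presence-probability clamp at 0.8 keeps the
dereplication overlap `shared/min` of unrelated genomes below the 0.9
threshold; without it, single-linkage clustering percolates and collapses
the PP reference panel to a single genome. Under strong co-inheritance a
collapse can still occasionally occur when a small genome is dominated by
one co-inherited pathway — a genuine fragility of min-normalized overlap
with single linkage, visible as occasional low-AUC seeds rather than hidden.

What a green test establishes — and what it does not: the generator
produces independent, single-channel signals with Gaussian/uniform noise
and a clean two-level annotation where every protein has exactly one
pathway. Real data couple the channels (operons are co-expressed and
co-inherited), contain paralogy, horizontal transfer, multi-pathway
proteins and annotation bias; none of that is emulated. Calibration and
recovery results on this world validate the *implementation*, not the
biological accuracy of the methods.

## Calibration and recovery (computed by the test suite)

The acceptance tests (`tests/testthat/test-acceptance.R`) verify, over 20
seeds of the default world: with all four knobs at 0 every scorer's mean
AUC against truth lies in [0.45, 0.55]; with all knobs at 0.9 every scorer's
mean AUC is at least 0.70; and the GM correction leaves unlinked corrected
matrices near-uncorrelated (|mean PCC| < 0.15) while raw matrices on a
shared tree correlate strongly. `scripts/acceptance.R` recomputes the
headline quantities from scratch.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive bp; ranks 0-based; chromosomes
  circular. Duplicate reciprocal-best-hit rows keep the higher bit score
  (logged). Multi-replicon genomes are out of scope.
- Score files round-trip at 9 significant digits and carry the method,
  configuration hash and seed in `#` comments; synthetic-world exports use
  `%.17g` so re-import is bit-exact, and identical configurations export
  byte-identical files.
- Two proteins mapping to the same gene in a genome contribute no
  distance from that genome (logged); a pair with no informative genome is
  undefined, score 0.
- The pipeline report (`report.json`) contains only reproducible content —
  no timestamps — so re-running with unchanged inputs is byte-identical;
  wall-clock time is reported on the returned R object only.
- `run_pipeline()` always persists stage intermediates (world files, score
  tables) so every reported number can be recomputed from files; the
  pipeline tests do exactly that.

## Known limitations

- The PP normalization scheme and the genome-distance formula are declared
  stand-ins for choices the underlying methods literature leaves
  under-specified; both are isolated behind single functions.
- The GM rescale-by-maximum-PCC correction removes the tree signal exactly
  only when protein matrices and `DG` are on commensurate scales; with
  strongly heterogeneous evolutionary rates residual tree signal survives.
- Dereplication by min-normalized overlap with single linkage can
  percolate; the spec-level 0.90 threshold is kept, and affected runs are
  visible in the logs.
- No statistical significance machinery (the benchmark reports AUCs, not
  confidence intervals).

## A worked example

```{r example}
cfg <- world_config(seed = 42)
world <- simulate_world(cfg)
tables <- score_world(world)
gold <- build_global_gold(world$annotation)
sapply(tables, function(tab) roc_curve(tab, gold)$auc)
```
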