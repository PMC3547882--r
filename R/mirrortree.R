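# Genome distance-corrected Mirrortree (GM): per-protein inter-species
# distance matrices, the shared-ortholog genome-distance matrix, removal of
# the speciation signal, and matrix correlation.

#' Construct/validate a labeled distance matrix
#'
#' @param values square numeric matrix with species ids as dimnames,
#'   symmetric with zero diagonal
#' @param label protein id, or `"GENOME"` for the genome-distance matrix
#' @param allow_negative corrected matrices may contain negative entries;
#'   raw distances may not
#' @return the matrix with a `label` attribute, class `distance_matrix`
#' @export
distance_matrix <- function(values, label, allow_negative = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  sp <- rownames(values)
  if (is.null(sp) || is.null(colnames(values)) ||
      !identical(sp, colnames(values))) {
    stop("distance_matrix: need identical row/column species names",
         call. = FALSE)
  }
  if (anyDuplicated(sp)) stop("distance_matrix: duplicate species ids",
                              call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) {
    stop("distance_matrix: matrix not symmetric", call. = FALSE)
  }
  if (any(diag(values) != 0)) {
    stop("distance_matrix: diagonal must be exactly 0", call. = FALSE)
  }
  if (!allow_negative && any(values < 0)) {
    stop("distance_matrix: negative distances not allowed", call. = FALSE)
  }
  values <- (values + t(values)) / 2  # remove sub-tolerance asymmetry
  diag(values) <- 0
  structure(values, label = label,
            class = c("distance_matrix", "matrix", "array"))
}

#' p-distance matrix from a multiple sequence alignment
#'
#' Pairwise p-distances: mismatching positions divided by the number of
#' alignment columns where both sequences are non-gap.  Gap characters are
#' `-` and `.`.
#'
#' @param msa named character vector of aligned sequences (equal length),
#'   names = species ids; or a `Biostrings::AAStringSet`-like object
#'   coercible with `as.character`
#' @param label protein id attached to the matrix
#' @return a [distance_matrix()]
#' @export
distance_matrix_from_alignment <- function(msa, label = "protein") {
  nm <- names(msa)
  msa <- as.character(msa)
  names(msa) <- nm
  if (is.null(names(msa)) || any(!nzchar(names(msa)))) {
    stop("distance_matrix_from_alignment: sequences must be named by species",
         call. = FALSE)
  }
  if (anyDuplicated(names(msa))) {
    stop("distance_matrix_from_alignment: duplicate species keys",
         call. = FALSE)
  }
  if (length(msa) < 2L) {
    stop("distance_matrix_from_alignment: need >= 2 sequences", call. = FALSE)
  }
  if (length(unique(nchar(msa))) != 1L) {
    stop("distance_matrix_from_alignment: aligned lengths differ",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  nongap <- !(chars %in% c("-", ".")); dim(nongap) <- dim(chars)
  n <- length(msa)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- nongap[i, ] & nongap[j, ]
      if (!any(ok)) {
        stop(sprintf(
          "distance_matrix_from_alignment: no comparable columns between %s and %s",
          names(msa)[i], names(msa)[j]), call. = FALSE)
      }
      d <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
      D[i, j] <- D[j, i] <- d
    }
  }
  distance_matrix(D, label)
}

#' Shared-ortholog genome distance
#'
#' Distance between two genomes from their shared ortholog count:
#' `1 - n_shared / min(n_a, n_b)`, where `n_a` and `n_b` are the total
#' protein counts of the two genomes and `n_shared` the number of orthologs
#' they share.  Identical gene complements give 0, disjoint ones give 1.
#'
#' @param n_a,n_b positive protein counts of the two genomes
#' @param n_shared shared ortholog count, `0 <= n_shared <= min(n_a, n_b)`
#' @return numeric in `[0,1]`
#' @export
genome_distance <- function(n_a, n_b, n_shared) {
  stopifnot(all(n_a > 0), all(n_b > 0), all(n_shared >= 0))
  m <- pmin(n_a, n_b)
  if (any(n_shared > m)) {
    stop("genome_distance: n_shared exceeds min(n_a, n_b)", call. = FALSE)
  }
  1 - n_shared / m
}

#' Build the genome-distance matrix DG
#'
#' @param omap an [ortholog_map()] supplying per-genome protein counts
#' @param pairwise_shared data.frame with columns `genome_a`, `genome_b`,
#'   `shared` giving shared-ortholog counts for every unordered genome pair
#'   of the reference set
#' @param genome_ids genomes to include (default: all in `pairwise_shared`)
#' @return a [distance_matrix()] labeled `"GENOME"`
#' @export
build_genome_distance_matrix <- function(omap, pairwise_shared,
                                         genome_ids = NULL) {
  stopifnot(inherits(omap, "ortholog_map"))
  req <- c("genome_a", "genome_b", "shared")
  if (!all(req %in% names(pairwise_shared))) {
    stop("build_genome_distance_matrix: pairwise_shared needs columns ",
         paste(req, collapse = ","), call. = FALSE)
  }
  gids <- genome_ids %||%
    sort(unique(c(pairwise_shared$genome_a, pairwise_shared$genome_b)))
  counts <- omap$genome_protein_counts
  unknown <- setdiff(gids, names(counts))
  if (length(unknown)) {
    stop(sprintf("build_genome_distance_matrix: no protein count for %s",
                 paste(unknown, collapse = ",")), call. = FALSE)
  }
  keys <- pair_key(pairwise_shared$genome_a, pairwise_shared$genome_b)
  shared <- stats::setNames(pairwise_shared$shared, keys)
  n <- length(gids)
  D <- matrix(0, n, n, dimnames = list(gids, gids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- pair_key(gids[i], gids[j])
      if (!k %in% names(shared)) {
        stop(sprintf("build_genome_distance_matrix: missing shared count for %s/%s",
                     gids[i], gids[j]), call. = FALSE)
      }
      D[i, j] <- D[j, i] <-
        genome_distance(counts[[gids[i]]], counts[[gids[j]]], shared[[k]])
    }
  }
  distance_matrix(D, "GENOME")
}

#' Rescale factor for the speciation correction
#'
#' Protein matrices and the genome-distance matrix DG live on different
#' scales; before subtraction each protein matrix is divided by `rho`, the
#' highest Pearson correlation observed between DG and any protein distance
#' matrix (computed over the species common to both, upper triangles).
#'
#' @param dg the genome [distance_matrix()]
#' @param protein_matrices named list of protein [distance_matrix()] objects
#' @param min_common minimum common species for a correlation (default 3)
#' @return list with `rho` (the maximum PCC, in (0,1]) and `argmax_protein`
#' @export
compute_rescale_factor <- function(dg, protein_matrices, min_common = 3L) {
  stopifnot(inherits(dg, "distance_matrix"), length(protein_matrices) >= 1L)
  best <- -Inf; who <- NA_character_; any_ok <- FALSE
  for (p in names(protein_matrices)) {
    dx <- protein_matrices[[p]]
    common <- intersect(rownames(dx), rownames(dg))
    if (length(common) < min_common) next
    any_ok <- TRUE
    r <- pcc(upper_tri_vec(dx[common, common, drop = FALSE]),
             upper_tri_vec(dg[common, common, drop = FALSE]))
    if (is.finite(r) && r > best) { best <- r; who <- p }
  }
  if (!any_ok) {
    stop(sprintf("compute_rescale_factor: no protein matrix shares >= %d species with DG",
                 min_common), call. = FALSE)
  }
  if (!is.finite(best) || best <= 0) {
    stop("compute_rescale_factor: maximum PCC is non-positive; correction impossible",
         call. = FALSE)
  }
  list(rho = min(best, 1), argmax_protein = who)
}

#' Remove the speciation signal from a protein distance matrix
#'
#' On the species common to both matrices, the rescaled protein distance is
#' subtracted from the genome distance:
#' `corrected(i,j) = DG(i,j) - DX(i,j) / rho`.  The diagonal is forced to
#' 0; negative off-diagonal entries are retained (they are differences, not
#' distances).
#'
#' @param dx protein [distance_matrix()]
#' @param dg genome [distance_matrix()]
#' @param rescale list from [compute_rescale_factor()]
#' @param min_common minimum common species (default 3)
#' @return corrected [distance_matrix()] (negative entries allowed)
#' @export
correct_distance_matrix <- function(dx, dg, rescale, min_common = 3L) {
  stopifnot(inherits(dx, "distance_matrix"), inherits(dg, "distance_matrix"))
  common <- intersect(rownames(dx), rownames(dg))
  if (length(common) < min_common) {
    stop(sprintf("correct_distance_matrix: only %d common species (need >= %d)",
                 length(common), min_common), call. = FALSE)
  }
  corr <- dg[common, common, drop = FALSE] -
    dx[common, common, drop = FALSE] / rescale$rho
  diag(corr) <- 0
  distance_matrix(unclass(corr), attr(dx, "label"), allow_negative = TRUE)
}

#' Mirrortree scores from corrected distance matrices
#'
#' For each protein pair, the Pearson correlation of the upper-triangle
#' entries of the two corrected matrices over their common species, clamped
#' below at 0.  Pairs with fewer than `min_common_species` common species,
#' or with a constant (zero-variance) distance vector, are undefined with
#' score 0.
#'
#' @param pairs two-column data.frame (or matrix) of protein ids
#' @param corrected_matrices named list of corrected [distance_matrix()]
#'   objects (one per protein)
#' @param min_common_species minimum shared species (default 10)
#' @return a [pair_score_table()] with method `"GM"`
#' @export
gm_scores <- function(pairs, corrected_matrices, min_common_species = 10L) {
  pairs <- normalize_pairs(pairs)
  prots <- names(corrected_matrices)
  missing <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)), prots)
  if (length(missing)) {
    stop(sprintf("gm_scores: no corrected matrix for: %s",
                 paste(utils::head(missing, 5), collapse = ",")),
         call. = FALSE)
  }
  species <- sort(unique(unlist(lapply(corrected_matrices, rownames))))
  ns <- length(species)
  # lay every protein's matrix onto the common species grid; cells outside
  # its species set are NA.  A pairwise-complete correlation over the
  # grid's upper-triangle cells is then exactly the PCC over the upper
  # triangle restricted to the two proteins' common species.
  ut <- upper.tri(matrix(0, ns, ns))
  V <- matrix(NA_real_, length(prots), sum(ut),
              dimnames = list(prots, NULL))
  present <- matrix(FALSE, length(prots), ns,
                    dimnames = list(prots, species))
  for (p in prots) {
    dx <- corrected_matrices[[p]]
    full <- matrix(NA_real_, ns, ns, dimnames = list(species, species))
    sp <- rownames(dx)
    full[sp, sp] <- dx
    V[p, ] <- full[ut]
    present[p, sp] <- TRUE
  }
  common_counts <- tcrossprod(present * 1)
  C <- suppressWarnings(stats::cor(t(V), use = "pairwise.complete.obs"))
  dimnames(C) <- list(prots, prots)
  ia <- match(pairs$protein_a, prots); ib <- match(pairs$protein_b, prots)
  too_few <- common_counts[cbind(ia, ib)] < min_common_species
  score_table_from_matrix(pairs, prots, C, "GM", extra_undefined = too_few)
}

#' Write a labeled distance matrix as square TSV
#' @param dm a [distance_matrix()]
#' @param path output path
#' @param comments character vector of `#` comment lines
#' @export
write_distance_matrix <- function(dm, path, comments = character()) {
  stopifnot(inherits(dm, "distance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(sprintf("# label=%s", attr(dm, "label")), con)
  sp <- rownames(dm)
  writeLines(paste(c("species", sp), collapse = "\t"), con)
  body <- matrix(sprintf("%.17g", dm), nrow = nrow(dm))
  writeLines(paste(sp, apply(body, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path file path
#' @return a [distance_matrix()]
#' @export
read_distance_matrix <- function(path) {
  assert_file_exists(path, "read_distance_matrix")
  lines <- readLines(path, warn = FALSE)
  lab <- sub("^# label=", "", lines[grepl("^# label=", lines)])
  if (!length(lab)) lab <- "protein"
  df <- read_tsv_plain(path)
  sp <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  dimnames(m) <- list(sp, names(df)[-1L])
  distance_matrix(m, lab[[1L]], allow_negative = TRUE)
}
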