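# Domain types and file readers for genome tables, ortholog maps,
# expression matrices and pathway annotations.  All formats are
# tab-separated UTF-8 text with '#' comment lines.

#' Construct a genome gene table
#'
#' An ordered, stranded gene coordinate table for one circular replicon.
#' Genes are sorted by start coordinate and assigned 0-based ranks; the
#' Gene Neighbor and Gene Cluster scorers operate on these ranks and on the
#' intergenic gaps implied by the coordinates.
#'
#' @param genome_id single genome identifier
#' @param length_bp circular chromosome length in bp (positive integer)
#' @param genes data.frame with columns `gene_id`, `start`, `end`, `strand`
#'   (`+`/`-`); coordinates are 1-based inclusive
#' @return an object of class `genome_table`: a list with `genome_id`,
#'   `length_bp` and a `genes` data.frame carrying an additional 0-based
#'   `rank` column in ascending start order
#' @export
genome_table <- function(genome_id, length_bp, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp <= 0L) {
    stop("genome_table: length_bp must be a positive integer", call. = FALSE)
  }
  req <- c("gene_id", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("genome_table: genes must have columns gene_id,start,end,strand",
         call. = FALSE)
  }
  genes <- genes[req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$strand %in% c("+", "-")) {
      stop(sprintf("genome_table: malformed strand '%s' on row %d",
                   g$strand, i), call. = FALSE)
    }
    if (is.na(g$start) || is.na(g$end) || g$end < g$start) {
      stop(sprintf("genome_table: end < start on row %d", i), call. = FALSE)
    }
    if (g$end > length_bp) {
      stop(sprintf("genome_table: end > length_bp on row %d", i),
           call. = FALSE)
    }
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- which(duplicated(genes$gene_id))[1L]
    stop(sprintf("genome_table: duplicate gene_id '%s' on row %d",
                 genes$gene_id[dup], dup), call. = FALSE)
  }
  ord <- order(genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- seq_len(nrow(genes)) - 1L
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, length_bp = length_bp, genes = genes),
            class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("<genome_table> %s: %d genes on %d bp circular chromosome\n",
              x$genome_id, nrow(x$genes), x$length_bp))
  invisible(x)
}

#' Read a genome gene table
#'
#' Reads either the native PTT-like TSV (first non-comment line
#' `genome_id<TAB>length_bp`, then a header line and one row per gene:
#' `gene_id  start  end  strand`) or, for files ending in `.gff`/`.gff3`,
#' a GFF3 file whose `gene` features are converted (requires the
#' `rtracklayer` package; the chromosome length is taken from the
#' `##sequence-region` pragma).
#'
#' @param path file path
#' @return a [genome_table()]
#' @export
read_genome_table <- function(path) {
  assert_file_exists(path, "read_genome_table")
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    return(read_genome_table_gff3(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2L) {
    stop("read_genome_table: need a genome header line and a column header",
         call. = FALSE)
  }
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 2L) {
    stop("read_genome_table: first line must be genome_id<TAB>length_bp",
         call. = FALSE)
  }
  body <- lines[-(1:2)]  # line 2 is the column header
  if (!length(body)) stop("read_genome_table: no gene rows", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) {
    stop(sprintf("read_genome_table: malformed gene row %d", bad[1L]),
         call. = FALSE)
  }
  genes <- data.frame(
    gene_id = vapply(parts, `[[`, "", 1L),
    start   = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
    end     = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
    strand  = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  tryCatch(
    genome_table(hdr[[1L]], as.integer(hdr[[2L]]), genes),
    error = function(e) stop(sprintf("read_genome_table: %s (file %s)",
                                     conditionMessage(e), path),
                             call. = FALSE)
  )
}

read_genome_table_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_genome_table: GFF3 input requires the rtracklayer package",
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3", feature.type = "gene")
  if (!length(gr)) stop("read_genome_table: no gene features in GFF3",
                        call. = FALSE)
  seqs <- as.character(unique(GenomeInfoDb::seqnames(gr)))
  if (length(seqs) != 1L) {
    stop("read_genome_table: multi-replicon GFF3 not supported; found: ",
         paste(seqs, collapse = ", "), call. = FALSE)
  }
  len <- GenomeInfoDb::seqlengths(gr)[seqs]
  if (is.na(len)) {
    # rtracklayer does not always propagate the pragma; read it directly
    pragma <- grep("^##sequence-region", readLines(path, warn = FALSE),
                   value = TRUE)
    parts <- strsplit(pragma, "\\s+")
    hit <- parts[vapply(parts, function(p) length(p) >= 4L && p[[2L]] == seqs,
                        logical(1))]
    if (length(hit)) len <- as.integer(hit[[1L]][[4L]])
  }
  if (is.na(len)) {
    stop("read_genome_table: GFF3 lacks a ##sequence-region length",
         call. = FALSE)
  }
  ids <- gr$ID %||% gr$Name
  if (is.null(ids) || anyNA(ids)) {
    stop("read_genome_table: GFF3 gene features need ID or Name attributes",
         call. = FALSE)
  }
  genome_table(seqs, as.integer(len), data.frame(
    gene_id = as.character(ids),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Write a genome gene table in the native TSV format
#' @param x a [genome_table()]
#' @param path output path
#' @param comments character vector of `#` comment lines (without the `#`)
#'   written at the top of the file
#' @export
write_genome_table <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "genome_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(c(paste(x$genome_id, x$length_bp, sep = "\t"),
               "gene_id\tstart\tend\tstrand"), con)
  utils::write.table(x$genes[c("gene_id", "start", "end", "strand")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Construct an ortholog map
#'
#' Holds, for every query protein, its reciprocal-best-hit ortholog per
#' reference genome with raw and self alignment bit scores, plus the total
#' protein count of every genome (the n_A / n_B inputs of the genome
#' distance).  BLAST-level filtering (e-value, bit-score floor) is assumed
#' to have been applied upstream; this container ingests the filtered table.
#'
#' @param entries data.frame with columns `query_id`, `genome_id`,
#'   `ortholog_gene_id`, `bit_score`, `self_bit_score`
#' @param genome_protein_counts named positive integer vector, one entry per
#'   genome id
#' @return object of class `ortholog_map`
#' @export
ortholog_map <- function(entries, genome_protein_counts) {
  req <- c("query_id", "genome_id", "ortholog_gene_id", "bit_score",
           "self_bit_score")
  if (!all(req %in% names(entries))) {
    stop("ortholog_map: entries must have columns ", paste(req, collapse = ","),
         call. = FALSE)
  }
  entries <- entries[req]
  entries$query_id <- as.character(entries$query_id)
  entries$genome_id <- as.character(entries$genome_id)
  entries$ortholog_gene_id <- as.character(entries$ortholog_gene_id)
  entries$bit_score <- as.numeric(entries$bit_score)
  entries$self_bit_score <- as.numeric(entries$self_bit_score)
  if (any(!is.finite(entries$bit_score)) || any(entries$bit_score <= 0)) {
    bad <- which(!is.finite(entries$bit_score) | entries$bit_score <= 0)[1L]
    stop(sprintf("ortholog_map: non-positive bit_score on row %d", bad),
         call. = FALSE)
  }
  if (any(!is.finite(entries$self_bit_score)) ||
      any(entries$self_bit_score <= 0)) {
    stop("ortholog_map: self_bit_score must be positive", call. = FALSE)
  }
  k <- paste(entries$query_id, entries$genome_id, sep = "\x1f")
  if (anyDuplicated(k)) {
    # duplicate RBH rows: keep the higher bit score (RBH should be unique;
    # the stronger alignment is the conservative survivor)
    lk_log(sprintf("ortholog_map: %d duplicate (query,genome) rows resolved by higher bit score",
                   sum(duplicated(k))), level = "info")
    ord <- order(k, -entries$bit_score)
    entries <- entries[ord, , drop = FALSE]
    entries <- entries[!duplicated(paste(entries$query_id, entries$genome_id,
                                         sep = "\x1f")), , drop = FALSE]
  }
  rownames(entries) <- NULL
  counts <- genome_protein_counts
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("ortholog_map: genome_protein_counts must be named", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(is.na(counts) | counts <= 0L)) {
    stop("ortholog_map: genome_protein_counts must be positive integers",
         call. = FALSE)
  }
  structure(list(entries = entries, genome_protein_counts = counts),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d entries, %d query proteins, %d genomes\n",
              nrow(x$entries), length(unique(x$entries$query_id)),
              length(x$genome_protein_counts)))
  invisible(x)
}

#' Read an ortholog map
#'
#' @param path TSV with header and columns `query_id`, `genome_id`,
#'   `ortholog_gene_id`, `bit_score`, `self_bit_score`
#' @param counts_path TSV with header and columns `genome_id`, `n_proteins`
#' @return an [ortholog_map()]
#' @export
read_ortholog_map <- function(path, counts_path) {
  assert_file_exists(path, "read_ortholog_map")
  assert_file_exists(counts_path, "read_ortholog_map")
  entries <- read_tsv_plain(path)
  cnt <- read_tsv_plain(counts_path)
  if (!all(c("genome_id", "n_proteins") %in% names(cnt))) {
    stop("read_ortholog_map: counts table needs columns genome_id,n_proteins",
         call. = FALSE)
  }
  ortholog_map(entries, stats::setNames(cnt$n_proteins, cnt$genome_id))
}

#' Write an ortholog map (two files)
#'
#' Bit scores are printed with `%.17g` so a write/read round trip restores
#' the doubles bit-exactly.
#'
#' @param x an [ortholog_map()]
#' @param path,counts_path output paths for the entries and the per-genome
#'   protein counts
#' @param comments character vector of `#` comment lines for both files
#' @export
write_ortholog_map <- function(x, path, counts_path, comments = character()) {
  stopifnot(inherits(x, "ortholog_map"))
  ent <- x$entries[order(x$entries$query_id, x$entries$genome_id), ]
  con <- file(path, "w")
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines("query_id\tgenome_id\tortholog_gene_id\tbit_score\tself_bit_score",
             con)
  if (nrow(ent)) {
    writeLines(sprintf("%s\t%s\t%s\t%.17g\t%.17g", ent$query_id,
                       ent$genome_id, ent$ortholog_gene_id, ent$bit_score,
                       ent$self_bit_score), con)
  }
  close(con)
  cnt <- data.frame(genome_id = names(x$genome_protein_counts),
                    n_proteins = unname(x$genome_protein_counts))
  cnt <- cnt[order(cnt$genome_id), ]
  con <- file(counts_path, "w")
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(c("genome_id\tn_proteins",
               sprintf("%s\t%d", cnt$genome_id, cnt$n_proteins)), con)
  close(con)
  invisible(path)
}

#' Read a genes-by-conditions expression matrix
#'
#' TSV with gene ids in the first column and condition ids in the header.
#' Empty cells become `NA`; rows with fewer than two finite values are
#' dropped (and logged) because no correlation can be computed from them.
#'
#' @param path file path
#' @return numeric matrix, rows = genes, columns = conditions, `NA` marking
#'   missing measurements
#' @export
read_expression_matrix <- function(path) {
  assert_file_exists(path, "read_expression_matrix")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE, row.names = NULL,
                          na.strings = c("", "NA"))
  cond <- names(df)[-1L]
  if (anyDuplicated(cond)) {
    stop(sprintf("read_expression_matrix: duplicate condition id '%s'",
                 cond[duplicated(cond)][1L]), call. = FALSE)
  }
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop(sprintf("read_expression_matrix: duplicate gene id '%s'",
                 genes[duplicated(genes)][1L]), call. = FALSE)
  }
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  dimnames(m) <- list(genes, cond)
  nfin <- rowSums(is.finite(m))
  drop <- nfin < 2L
  if (any(drop)) {
    lk_log(sprintf("read_expression_matrix: dropped %d gene(s) with <2 finite values: %s",
                   sum(drop), paste(genes[drop], collapse = ",")))
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' Write an expression matrix in the TSV dialect read by
#' [read_expression_matrix()]
#'
#' Values are printed with `%.17g` (missing values as empty cells) so the
#' round trip is bit-exact.
#'
#' @param m numeric matrix with gene row names and condition column names
#' @param path output path
#' @param comments character vector of `#` comment lines
#' @export
write_expression_matrix <- function(m, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  body[!is.finite(m)] <- ""
  writeLines(paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Construct a two-level pathway annotation
#'
#' KEGG-orthology-like structure: each protein carries one or more
#' (level-2 category, level-3 pathway) memberships, and every level-3
#' pathway belongs to exactly one level-2 category.
#'
#' @param df data.frame with columns `protein_id`, `level2`, `level3`
#' @return object of class `pathway_annotation` (a normalized data.frame)
#' @export
pathway_annotation <- function(df) {
  req <- c("protein_id", "level2", "level3")
  if (!all(req %in% names(df))) {
    stop("pathway_annotation: need columns protein_id,level2,level3",
         call. = FALSE)
  }
  df <- df[req]
  for (cl in req) df[[cl]] <- as.character(df[[cl]])
  map <- unique(df[c("level3", "level2")])
  dup <- map$level3[duplicated(map$level3)]
  if (length(dup)) {
    rows <- which(df$level3 == dup[1L])
    stop(sprintf(
      "pathway_annotation: pathway '%s' listed under two categories (%s); rows %s",
      dup[1L], paste(unique(df$level2[rows]), collapse = " and "),
      paste(rows[1:2], collapse = ",")), call. = FALSE)
  }
  df <- unique(df)
  df <- df[order(df$protein_id, df$level2, df$level3), ]
  rownames(df) <- NULL
  class(df) <- c("pathway_annotation", "data.frame")
  df
}

#' Read a pathway annotation table
#' @param path TSV with header and columns `protein_id`, `level2`, `level3`
#' @return a [pathway_annotation()]
#' @export
read_pathway_annotations <- function(path) {
  assert_file_exists(path, "read_pathway_annotations")
  pathway_annotation(read_tsv_plain(path))
}

#' Write a pathway annotation table
#' @param x a [pathway_annotation()]
#' @param path output path
#' @param comments character vector of `#` comment lines
#' @export
write_pathway_annotations <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "pathway_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(c("protein_id\tlevel2\tlevel3",
               sprintf("%s\t%s\t%s", x$protein_id, x$level2, x$level3)), con)
  invisible(path)
}

#' Annotated proteins of a pathway annotation
#' @param x a [pathway_annotation()]
#' @return sorted character vector of protein ids
#' @export
annotated_proteins <- function(x) {
  stopifnot(inherits(x, "pathway_annotation"))
  sort(unique(x$protein_id))
}
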