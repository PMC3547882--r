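# Pair score tables: the common output container of all five scorers.

#' Construct a pair score table
#'
#' Per-pair interaction scores on the 0-1 scale produced by one prediction
#' method.  Pairs are unordered: ids are normalized so `protein_a <
#' protein_b`.  Pairs the method could not evaluate (no co-occurring
#' genome, zero-variance profile, too few common species, ...) carry score
#' 0 and `undefined = TRUE`; keeping them in the table keeps every method
#' evaluated over the identical pair universe downstream.
#'
#' @param protein_a,protein_b character vectors of protein ids
#' @param score numeric scores in `[0,1]`
#' @param undefined logical; `TRUE` where the method could not score the pair
#' @param method one of `"GN"`, `"GC"`, `"PP"`, `"GM"`, `"ES"`
#' @param seed optional integer recorded in file headers
#' @param config_hash optional fingerprint recorded in file headers
#' @return data.frame of class `pair_score_table` with attributes `method`,
#'   `seed`, `config_hash`
#' @export
pair_score_table <- function(protein_a, protein_b, score,
                             undefined = rep(FALSE, length(score)),
                             method = c("GN", "GC", "PP", "GM", "ES"),
                             seed = NA_integer_, config_hash = NA_character_) {
  method <- match.arg(method)
  protein_a <- as.character(protein_a)
  protein_b <- as.character(protein_b)
  if (any(protein_a == protein_b)) {
    stop("pair_score_table: self-pairs are not allowed", call. = FALSE)
  }
  a <- pmin(protein_a, protein_b)
  b <- pmax(protein_a, protein_b)
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    stop("pair_score_table: scores must be finite and in [0,1]", call. = FALSE)
  }
  k <- pair_key(a, b)
  if (anyDuplicated(k)) {
    stop(sprintf("pair_score_table: duplicate pair %s",
                 sub("\x1f", "/", k[duplicated(k)][1L])), call. = FALSE)
  }
  df <- data.frame(protein_a = a, protein_b = b, score = score,
                   undefined = as.logical(undefined),
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein_a, df$protein_b), ]
  rownames(df) <- NULL
  structure(df, method = method, seed = seed, config_hash = config_hash,
            class = c("pair_score_table", "data.frame"))
}

#' @export
print.pair_score_table <- function(x, ...) {
  cat(sprintf("<pair_score_table> method=%s, %d pairs (%d undefined)\n",
              attr(x, "method"), nrow(x), sum(x$undefined)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Look up scores for a set of pairs
#' @param table a [pair_score_table()]
#' @param a,b protein id vectors
#' @return numeric score vector (`NA` for pairs absent from the table)
#' @export
scores_for <- function(table, a, b) {
  stopifnot(inherits(table, "pair_score_table"))
  idx <- match(pair_key(a, b), pair_key(table$protein_a, table$protein_b))
  table$score[idx]
}

#' Write a pair score table
#'
#' TSV with columns `protein_a`, `protein_b`, `score`, `undefined` (0/1),
#' preceded by `#` header comments recording the method, configuration
#' fingerprint and RNG seed.  Scores are printed at 9 significant digits so
#' write/read round-trips are exact at that precision.
#'
#' @param table a [pair_score_table()]
#' @param path output path
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "pair_score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# method=%s", attr(table, "method")),
    sprintf("# config_hash=%s", attr(table, "config_hash") %||% NA),
    sprintf("# seed=%s", attr(table, "seed") %||% NA),
    "protein_a\tprotein_b\tscore\tundefined"), con)
  if (nrow(table)) {
    writeLines(sprintf("%s\t%s\t%.9g\t%d", table$protein_a, table$protein_b,
                       table$score, as.integer(table$undefined)), con)
  }
  invisible(path)
}

#' Read a pair score table written by [write_score_table()]
#'
#' Pair order within a row is normalized on read; a pair listed twice is
#' rejected.
#'
#' @param path file path
#' @return a [pair_score_table()]
#' @export
read_score_table <- function(path) {
  assert_file_exists(path, "read_score_table")
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^# ", lines)]
  get_meta <- function(key) {
    hit <- sub(sprintf("^# %s=", key), "", meta[grepl(sprintf("^# %s=", key), meta)])
    if (length(hit)) hit[[1L]] else NA_character_
  }
  df <- read_tsv_plain(path)
  if (!all(c("protein_a", "protein_b", "score") %in% names(df))) {
    stop("read_score_table: need columns protein_a,protein_b,score",
         call. = FALSE)
  }
  und <- if ("undefined" %in% names(df)) as.logical(df$undefined) else
    rep(FALSE, nrow(df))
  method <- get_meta("method")
  if (is.na(method)) stop("read_score_table: missing '# method=' header",
                          call. = FALSE)
  seed <- suppressWarnings(as.integer(get_meta("seed")))
  pair_score_table(df$protein_a, df$protein_b, df$score, und, method = method,
                   seed = seed, config_hash = get_meta("config_hash"))
}

# Assemble a pair score table from a full symmetric score matrix computed
# over `proteins`, extracting only the requested pairs.  `cmat` may contain
# NA for undefined pairs; `extra_undefined` marks pairs undefined for
# other reasons (e.g. too few common species).  Used internally by the
# vectorized scorers.
score_table_from_matrix <- function(pairs, proteins, cmat, method,
                                    extra_undefined = NULL) {
  ia <- match(pairs$protein_a, proteins)
  ib <- match(pairs$protein_b, proteins)
  if (anyNA(ia) || anyNA(ib)) {
    miss <- unique(c(pairs$protein_a[is.na(ia)], pairs$protein_b[is.na(ib)]))
    stop(sprintf("scorer: protein(s) not in input: %s",
                 paste(utils::head(miss, 5), collapse = ",")), call. = FALSE)
  }
  raw <- cmat[cbind(ia, ib)]
  und <- !is.finite(raw)
  if (!is.null(extra_undefined)) und <- und | extra_undefined
  sc <- clamp_low(ifelse(und, 0, raw))
  sc <- pmin(sc, 1)
  pair_score_table(pairs$protein_a, pairs$protein_b, sc, und, method = method)
}

# Normalize a pairs argument (2-column data.frame/matrix of protein ids)
# into a data.frame with protein_a < protein_b and no duplicates/self pairs.
normalize_pairs <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  if (any(a == b)) stop("pairs: self-pairs are not allowed", call. = FALSE)
  df <- data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df[order(df$protein_a, df$protein_b), , drop = FALSE]
}

#' All unordered pairs of a protein set
#' @param proteins character vector of ids
#' @return data.frame with columns `protein_a`, `protein_b`
#' @export
all_pairs <- function(proteins) {
  proteins <- sort(unique(as.character(proteins)))
  n <- length(proteins)
  if (n < 2L) return(data.frame(protein_a = character(), protein_b = character()))
  idx <- utils::combn(n, 2L)
  data.frame(protein_a = proteins[idx[1L, ]], protein_b = proteins[idx[2L, ]],
             stringsAsFactors = FALSE)
}
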