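# End-to-end orchestration: simulate (or load) -> score -> evaluate ->
# report.

#' Score a world with one or more methods
#'
#' Runs the requested scorers over a pair universe (by default every
#' unordered pair of annotated proteins, i.e. the global gold-standard
#' universe) using the inputs bundled in a `synthetic_world` (or any list
#' with the same fields built from real inputs).
#'
#' GM proteins whose distance matrices share fewer than 3 species with the
#' genome-distance matrix cannot be corrected; their pairs are emitted as
#' undefined with score 0.
#'
#' @param world a `synthetic_world` (or compatible list with fields
#'   `annotation`, `genomes`, `ortholog_map`, `expression`,
#'   `dist_matrices`, `genome_shared`)
#' @param methods character subset of `c("GN","GC","PP","GM","ES")`
#' @param pairs optional explicit pair universe (two-column data.frame)
#' @param config a [run_config()]
#' @return named list of [pair_score_table()] objects
#' @export
score_world <- function(world, methods = c("GN", "GC", "PP", "GM", "ES"),
                        pairs = NULL, config = run_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  pairs <- normalize_pairs(pairs %||% all_pairs(annotated_proteins(world$annotation)))
  proteins <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      GN = gn_scores(pairs, world$ortholog_map, world$genomes),
      GC = gc_scores(pairs, world$ortholog_map, world$genomes,
                     max_gap = config$intergenic_cutoff),
      PP = {
        refs <- select_reference_genomes(world$ortholog_map, proteins,
                                         config$dereplicate_threshold)
        P <- build_profile_matrix(world$ortholog_map, proteins, refs)
        pp_scores(pairs, normalize_profile_matrix(P, world$ortholog_map))
      },
      GM = score_gm(pairs, world, config),
      ES = {
        E <- select_varying_conditions(world$expression,
                                       config$top_k_conditions)
        es_scores(pairs, E)
      })
  }
  out
}

# Full GM route: genome-distance matrix -> rescale factor -> per-protein
# correction -> pairwise matrix correlation.
score_gm <- function(pairs, world, config = run_config()) {
  dg <- build_genome_distance_matrix(world$ortholog_map, world$genome_shared)
  dmats <- world$dist_matrices
  proteins <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  missing <- setdiff(proteins, names(dmats))
  if (length(missing)) {
    stop(sprintf("score_gm: no distance matrix for: %s",
                 paste(utils::head(missing, 5), collapse = ",")),
         call. = FALSE)
  }
  dmats <- dmats[proteins]
  rescale <- compute_rescale_factor(dg, dmats)
  corrected <- list()
  for (p in proteins) {
    co <- tryCatch(correct_distance_matrix(dmats[[p]], dg, rescale),
                   error = function(e) NULL)
    if (!is.null(co)) corrected[[p]] <- co
  }
  ok <- pairs$protein_a %in% names(corrected) &
    pairs$protein_b %in% names(corrected)
  tabs <- list()
  if (any(ok)) {
    tabs$scored <- gm_scores(pairs[ok, , drop = FALSE], corrected,
                             config$min_common_species)
  }
  if (any(!ok)) {
    lk_log(sprintf("score_gm: %d pair(s) undefined (uncorrectable matrices)",
                   sum(!ok)))
    bad <- pairs[!ok, , drop = FALSE]
    tabs$undef <- pair_score_table(bad$protein_a, bad$protein_b,
                                   rep(0, nrow(bad)), rep(TRUE, nrow(bad)),
                                   method = "GM")
  }
  if (length(tabs) == 1L) return(tabs[[1L]])
  joined <- rbind(as.data.frame(tabs$scored), as.data.frame(tabs$undef))
  pair_score_table(joined$protein_a, joined$protein_b, joined$score,
                   joined$undefined, method = "GM")
}

#' Run the full pipeline
#'
#' Stages: (1) simulate a synthetic world from `world_cfg` or load real
#' inputs from `inputs`; (2) score all requested methods over the global
#' gold universe, persisting one score table per method; (3) evaluate:
#' global and per-category gold standards, per-category ROC/AUC matrix,
#' and a TP/FP threshold series on the global gold standard.  Outputs
#' (`auc_summary.tsv`, `tp_fp_series.tsv`, `report.json`, `scores/*.tsv`,
#' and in synthetic mode `world/`) are deterministic functions of the
#' configuration, so re-running with unchanged inputs reproduces identical
#' files.
#'
#' @param out_dir output directory (created)
#' @param world_cfg a [world_config()] (synthetic mode), or `NULL`
#' @param inputs real mode: named list with `genomes_dir`, `orthologs`,
#'   `genome_counts`, `expression`, `annotations`, `dist_matrices_dir`,
#'   `genome_shared`
#' @param config a [run_config()]; `config$methods` selects the scorers
#' @param thresholds threshold grid for the TP/FP series
#' @return object of class `pipeline_report`: list with `auc` (matrix),
#'   `tp_fp` (data.frame), `manifest` (file -> content hash), `config`,
#'   `files`
#' @export
run_pipeline <- function(out_dir, world_cfg = NULL, inputs = NULL,
                         config = run_config(),
                         thresholds = seq(0, 1, by = 0.02)) {
  if (is.null(world_cfg) == is.null(inputs)) {
    stop("run_pipeline: give exactly one of world_cfg (synthetic mode) or inputs (real mode)",
         call. = FALSE)
  }
  dir.create(file.path(out_dir, "scores"), recursive = TRUE,
             showWarnings = FALSE)
  if (!is.null(world_cfg)) {
    lk_log("stage simulate: generating synthetic world")
    world <- simulate_world(world_cfg)
    export_world(world, file.path(out_dir, "world"))
  } else {
    world <- load_real_inputs(inputs, config$methods)
  }
  lk_log(sprintf("stage score: methods %s", paste(config$methods, collapse = ",")))
  tables <- withCallingHandlers(
    score_world(world, config$methods, config = config),
    error = function(e) stop(sprintf("stage score failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  for (m in names(tables)) {
    attr(tables[[m]], "seed") <- config$seed
    attr(tables[[m]], "config_hash") <- config$hash
    write_score_table(tables[[m]],
                      file.path(out_dir, "scores", paste0(m, ".tsv")))
  }
  lk_log("stage evaluate: gold standards and ROC/AUC")
  ann <- world$annotation
  cats <- sort(unique(ann$level2))
  golds <- stats::setNames(
    lapply(cats, function(cc) build_pathway_gold(ann, cc, cats)), cats)
  auc <- auc_summary(tables, golds)
  global <- build_global_gold(ann)
  series <- lapply(names(tables), function(m) {
    cbind(method = m, tp_fp_series(tables[[m]], global, thresholds))
  })
  series <- do.call(rbind, series)
  utils::write.table(
    data.frame(category = rownames(auc), round(auc, 6), check.names = FALSE),
    file.path(out_dir, "auc_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(series, file.path(out_dir, "tp_fp_series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "report.json")
  manifest <- vapply(files, function(f) {
    fnv1a_hash(rawToChar(readBin(file.path(out_dir, f), "raw",
                                 file.size(file.path(out_dir, f)))))
  }, character(1))
  report <- list(
    config = unclass(config)[setdiff(names(config), "hash")],
    config_hash = config$hash,
    mode = if (is.null(world_cfg)) "real" else "synthetic",
    auc = as.data.frame(auc),
    manifest = as.list(manifest))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(auc = auc, tp_fp = series, manifest = manifest,
                 config = config,
                 files = file.path(out_dir, c("auc_summary.tsv",
                                              "tp_fp_series.tsv",
                                              "report.json"))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\nAUC summary:\n")
  print(round(x$auc, 3))
  invisible(x)
}

# Assemble a world-shaped input list from real file paths, failing with the
# stage and file name when something is missing.
load_real_inputs <- function(inputs, methods) {
  need <- c(annotations = "evaluate")
  if (any(c("GN", "GC") %in% methods)) {
    need <- c(need, genomes_dir = "GN/GC", orthologs = "GN/GC",
              genome_counts = "GN/GC")
  }
  if ("PP" %in% methods) {
    need <- c(need, orthologs = "PP", genome_counts = "PP")
  }
  if ("GM" %in% methods) {
    need <- c(need, dist_matrices_dir = "GM", genome_shared = "GM",
              orthologs = "GM", genome_counts = "GM")
  }
  if ("ES" %in% methods) need <- c(need, expression = "ES")
  for (k in unique(names(need))) {
    if (is.null(inputs[[k]]) || !file.exists(inputs[[k]])) {
      stop(sprintf("stage %s failed: missing input '%s' (%s)",
                   need[[k]], k, inputs[[k]] %||% "not given"),
           call. = FALSE)
    }
  }
  world <- list(annotation = read_pathway_annotations(inputs$annotations))
  if (!is.null(inputs$genomes_dir)) {
    gfiles <- sort(list.files(inputs$genomes_dir, full.names = TRUE,
                              pattern = "\\.(tsv|gff3?)$"))
    world$genomes <- lapply(gfiles, read_genome_table)
    names(world$genomes) <- vapply(world$genomes, `[[`, "", "genome_id")
  }
  if (!is.null(inputs$orthologs)) {
    world$ortholog_map <- read_ortholog_map(inputs$orthologs,
                                            inputs$genome_counts)
  }
  if (!is.null(inputs$expression)) {
    world$expression <- read_expression_matrix(inputs$expression)
  }
  if (!is.null(inputs$dist_matrices_dir)) {
    dfiles <- sort(list.files(inputs$dist_matrices_dir, full.names = TRUE))
    world$dist_matrices <- lapply(dfiles, read_distance_matrix)
    names(world$dist_matrices) <- vapply(world$dist_matrices, attr, "",
                                         "label")
  }
  if (!is.null(inputs$genome_shared)) {
    world$genome_shared <- read_tsv_plain(inputs$genome_shared)
  }
  world
}
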