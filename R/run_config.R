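# Run configuration: the tunable parameters shared by the pipeline stages.

#' Construct a run configuration
#'
#' Bundles the scorer parameters, reference-set choices and RNG seed used
#' by [run_pipeline()].  Defaults follow the analysis conventions for
#' prokaryotic genome-context methods: operon-like clusters allow at most
#' 100 nt of intergenic DNA, expression similarity uses the 300 most
#' varying conditions, mirrortree correlations require at least 10 common
#' species, and near-redundant reference genomes are collapsed at 90%
#' ortholog overlap.
#'
#' @param intergenic_cutoff maximum intergenic gap (nt) inside a gene
#'   cluster
#' @param top_k_conditions number of most-varying expression conditions
#'   retained
#' @param min_common_species minimum species shared by two distance
#'   matrices for a mirrortree correlation
#' @param dereplicate_threshold ortholog-overlap fraction above which two
#'   reference genomes are clustered for dereplication
#' @param seed integer RNG seed recorded in all outputs
#' @param methods character subset of `c("GN","GC","PP","GM","ES")`
#' @return object of class `run_config`
#' @export
run_config <- function(intergenic_cutoff = 100L, top_k_conditions = 300L,
                       min_common_species = 10L,
                       dereplicate_threshold = 0.90, seed = 1L,
                       methods = c("GN", "GC", "PP", "GM", "ES")) {
  stopifnot(intergenic_cutoff > 0, top_k_conditions >= 2,
            min_common_species >= 3,
            dereplicate_threshold > 0, dereplicate_threshold <= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  cfg <- list(intergenic_cutoff = as.integer(intergenic_cutoff),
              top_k_conditions = as.integer(top_k_conditions),
              min_common_species = as.integer(min_common_species),
              dereplicate_threshold = dereplicate_threshold,
              seed = as.integer(seed), methods = methods)
  cfg$hash <- object_hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in setdiff(names(x), "hash")) {
    cat(sprintf("  %s: %s\n", k, paste(x[[k]], collapse = ",")))
  }
  cat(sprintf("  hash: %s\n", x$hash))
  invisible(x)
}
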