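# End-to-end pipeline orchestration: mentions -> counts -> p-values ->
# similarities -> network -> communities -> enrichment, with every
# intermediate written to an output directory and a JSON manifest
# recording the parameters that produced them.

#' Pipeline run configuration
#'
#' @param mentions_path mention TSV (see [read_mentions_tsv()]).
#' @param out_dir output directory for all artifacts.
#' @param cutoff either a number in \[0, 1\], or one of the named presets
#'   `"median"`, `"moderate"`, `"high"` which resolve to the 50th, 95th
#'   and 99th percentile of the run's own similarity distribution.
#' @param floor p-value truncation floor for weight profiles.
#' @param log_base logarithm base for weight profiles.
#' @param percentile_type interpolation rule for percentile cutoffs
#'   (passed to [stats::quantile()]).
#' @param seed integer seed (community detection, layout).
#' @param max_iter label-propagation sweep limit.
#' @param bonferroni_m optional Bonferroni family-size override.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mentions_path, out_dir, cutoff = "high",
                       floor = 1e-6, log_base = exp(1), percentile_type = 7,
                       seed = 1L, max_iter = 100L, bonferroni_m = NULL) {
  if (is.character(cutoff)) {
    if (!cutoff %in% names(.cutoff_presets)) {
      stop_("`cutoff` preset must be one of: ",
            paste(names(.cutoff_presets), collapse = ", "))
    }
  } else if (!is_prob(cutoff)) {
    stop_("`cutoff` must be a number in [0, 1] or a preset name")
  }
  if (!is_prob(floor) || floor <= 0 || floor >= 1) {
    stop_("`floor` must lie strictly between 0 and 1")
  }
  if (!is.numeric(log_base) || log_base <= 1) stop_("`log_base` must exceed 1")
  if (!percentile_type %in% 1:9) stop_("`percentile_type` must be in 1..9")
  if (!is_count(max_iter) || max_iter < 1) stop_("`max_iter` must be >= 1")
  if (!is.null(bonferroni_m) && (!is_count(bonferroni_m) || bonferroni_m < 1)) {
    stop_("`bonferroni_m` must be a count >= 1")
  }
  structure(
    list(mentions_path = mentions_path, out_dir = out_dir, cutoff = cutoff,
         floor = floor, log_base = log_base,
         percentile_type = as.integer(percentile_type),
         seed = as.integer(seed), max_iter = as.integer(max_iter),
         bonferroni_m = bonferroni_m),
    class = "run_config"
  )
}

# Named cutoff presets: percentile levels of the run's own similarity
# distribution (higher percentile = higher-confidence, sparser network).
.cutoff_presets <- c(median = 0.50, moderate = 0.95, high = 0.99)

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(y), allowed)
  if (length(extra) > 0) {
    stop_(path, ": unknown config field(s): ", paste(extra, collapse = ", "))
  }
  do.call(run_config, y)
}

#' Write a run configuration to YAML
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full association-network pipeline
#'
#' Reads mention records, tallies co-occurrence counts, computes the
#' gene-GO p-value matrix and gene-gene similarity matrix, thresholds
#' the network at the configured cutoff (resolving percentile presets
#' against the run's own similarity distribution), detects communities
#' by label propagation, scores community GO enrichment, and writes
#' every artifact plus a JSON manifest to `cfg$out_dir`. Deterministic
#' given the configuration, including the seed.
#'
#' @param cfg a [run_config()].
#' @param records optional list of [abstract_record()]s; when supplied,
#'   `cfg$mentions_path` is not read.
#' @return (invisibly) a list with elements `counts`, `pmat`, `sim`,
#'   `net`, `partition`, `enrichment`, `cutoff_value` and `manifest`.
#' @export
run_pipeline <- function(cfg, records = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  records <- records %||%
    stage("read_mentions", read_mentions_tsv(cfg$mentions_path))
  counts <- stage("tally", tally_counts(records))
  pmat <- stage("pvalues", build_pvalue_matrix(counts))
  sim <- stage("similarity",
               similarity_matrix(pmat, floor = cfg$floor,
                                 log_base = cfg$log_base))
  cutoff_value <- if (is.character(cfg$cutoff)) {
    stage("cutoff", similarity_percentiles(similarity_values(sim),
                                           .cutoff_presets[[cfg$cutoff]],
                                           type = cfg$percentile_type))
  } else {
    cfg$cutoff
  }
  net <- stage("network", build_network(sim, cutoff_value))
  partition <- stage("communities",
                     label_propagation(net, seed = cfg$seed,
                                       max_iter = cfg$max_iter))
  enrichment <- stage("enrichment", community_enrichment(pmat, partition))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  stage("write", {
    write_counts(counts, p("counts"))
    write_pvalues_tsv(pmat, p("pvalues.tsv"), matrix_path = p("pvalues_matrix.tsv"))
    write_similarity_tsv(sim, p("similarity.tsv"),
                         matrix_path = p("similarity_matrix.tsv"))
    write_network_tsv(net, p("network_edges.tsv"),
                      graphml_path = p("network.graphml"),
                      partition = partition)
    write_partition_tsv(partition, p("communities.tsv"))
    write_enrichment_tsv(enrichment, p("enrichment.tsv"))
  })

  manifest <- list(
    package = "litgonet",
    version = as.character(utils::packageVersion("litgonet")),
    seed = cfg$seed,
    parameters = list(
      cutoff = cfg$cutoff, cutoff_value = unname(cutoff_value),
      floor = cfg$floor, log_base = cfg$log_base,
      percentile_type = cfg$percentile_type, max_iter = cfg$max_iter
    ),
    inputs = list(mentions_path = cfg$mentions_path,
                  n_records = length(records)),
    results = list(
      n_total = counts$n_total,
      n_genes = length(counts$n_gene),
      n_go = length(counts$n_go),
      n_edges = igraph::ecount(net$graph),
      n_communities = length(unique(unclass(partition)))
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(counts = counts, pmat = pmat, sim = sim, net = net,
                 partition = partition, enrichment = enrichment,
                 cutoff_value = unname(cutoff_value), manifest = manifest))
}
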