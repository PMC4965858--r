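#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults reproduce the
#' published stringent criteria: probability >= 0.99, >= 2 unique peptides,
#' contaminant/decoy/cDNA-like exclusion, pseudocount 1.25, raw Fisher
#' p < 0.05 and |Rsc| > 2.
#'
#' @param report path to the protein report TSV.
#' @param annotation path to the sample annotation TSV.
#' @param out_dir output directory for run artifacts.
#' @param gene_sets optional GMT path enabling the enrichment stage.
#' @param reference reference group label (default: group of the first
#'   annotated sample).
#' @param filter a [filter_policy()].
#' @param pseudocount Rsc pseudocount `f`.
#' @param selection a [selection_policy()].
#' @param cor_method,cor_transform see [correlation_matrix()].
#' @param linkage see [cluster_samples()].
#' @param enrich_direction query direction for
#'   [build_query_from_differential()].
#' @param verbose emit progress messages.
#' @export
pipeline_config <- function(report, annotation, out_dir,
                            gene_sets = NULL, reference = NULL,
                            filter = filter_policy(), pseudocount = 1.25,
                            selection = selection_policy(),
                            cor_method = "pearson",
                            cor_transform = "log2cpm",
                            linkage = "average",
                            enrich_direction = "enriched",
                            verbose = TRUE) {
  structure(list(report = report, annotation = annotation,
                 out_dir = out_dir, gene_sets = gene_sets,
                 reference = reference, filter = filter,
                 pseudocount = pseudocount, selection = selection,
                 cor_method = cor_method, cor_transform = cor_transform,
                 linkage = linkage, enrich_direction = enrich_direction,
                 verbose = verbose),
            class = "pipeline_config")
}

stage <- function(cfg, name, expr) {
  if (cfg$verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full differential spectral-counting pipeline
#'
#' filter -> pool -> Rsc -> Fisher -> BH -> select -> categorize ->
#' presence breakdown -> correlation/clustering -> enrichment. Writes, under
#' `out_dir`: `differential.tsv`, `filter_report.tsv`, `partition.json`,
#' `presence.json`, `correlation.tsv`, `tree.nwk`, `enrichment.tsv` (if
#' gene sets were given) and `manifest.json` (config echo, package version,
#' per-stage record counts, the data-derived total ratio `N_ref/N_cmp`).
#' Fully deterministic for fixed inputs and config.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `differential`, `partition`, `presence`,
#'   `correlation`, `tree`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cm <- stage(config, "read", read_protein_report(
    config$report, config$annotation, reference = config$reference))
  n_input <- nrow(cm$counts)

  flt <- stage(config, "filter", apply_filters(cm, config$filter))
  cmf <- flt$matrix
  write_tsv(flt$report, file.path(config$out_dir, "filter_report.tsv"))

  diff <- stage(config, "differential",
                differential_analysis(cmf, f = config$pseudocount,
                                      policy = config$selection))
  write_differential_table(diff, file.path(config$out_dir,
                                           "differential.tsv"))

  part <- partition_summary(diff)
  cmp_group <- cmf$groups[2]
  enriched_acc <- diff$accession[diff$selected & diff$rsc > 0]
  diminished_acc <- diff$accession[diff$selected & diff$rsc < 0]
  presence <- stage(config, "presence", list(
    enriched_in_cmp = if (length(enriched_acc))
      presence_breakdown(cmf, enriched_acc, cmp_group) else NULL,
    diminished_in_cmp = if (length(diminished_acc))
      presence_breakdown(cmf, diminished_acc, cmp_group) else NULL))
  jsonlite::write_json(as.list(part),
                       file.path(config$out_dir, "partition.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(presence, file.path(config$out_dir, "presence.json"),
                       auto_unbox = TRUE, digits = NA)

  corr <- stage(config, "correlation",
                correlation_matrix(cmf, method = config$cor_method,
                                   transform = config$cor_transform))
  write_tsv(cbind(sample_id = rownames(corr),
                  as.data.frame(unclass(corr), check.names = FALSE)),
            file.path(config$out_dir, "correlation.tsv"))
  tree <- stage(config, "cluster", cluster_samples(corr, config$linkage))
  writeLines(to_newick(tree), file.path(config$out_dir, "tree.nwk"))

  overlap <- overlap_counts(cmf)
  jsonlite::write_json(overlap, file.path(config$out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- stage(config, "enrichment", {
      sets <- read_gmt(config$gene_sets)
      universe <- unique(cmf$meta$gene[nzchar(cmf$meta$gene)])
      query <- build_query_from_differential(diff, config$enrich_direction)
      if (length(query)) overrepresentation(query, sets, universe) else NULL
    })
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }

  manifest <- list(
    package = "speccount",
    version = as.character(utils::packageVersion("speccount")),
    config = serializable_config(config),
    groups = cmf$groups,
    total_ratio = attr(diff, "N_ref") / attr(diff, "N_cmp"),
    stages = list(
      input = n_input,
      filter = list(retained = nrow(cmf$counts),
                    removed = sum(flt$report$n_removed)),
      differential = list(tested = nrow(diff),
                          dropped_zero = attr(diff, "n_dropped"),
                          selected = sum(diff$selected)),
      partition = as.list(part)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(differential = diff, partition = part,
                 presence = presence, correlation = corr, tree = tree,
                 overlap = overlap, enrichment = enrichment,
                 manifest = manifest))
}

serializable_config <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out$selection <- unclass(out$selection)
  out
}
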