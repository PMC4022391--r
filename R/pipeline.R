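#' Resolved pipeline configuration
#'
#' Collects the stage parameters and I/O paths of a full run.  The
#' defaults reproduce the study settings of the marine analysis this
#' pipeline implements: annotation e-value < 1e-5 (identity filter off,
#' as for long-read data; set `min_identity = 75` for short-read virome
#' data), enrichment threshold P < 1e-4 with no multiple-testing
#' correction, superset design, motif thresholds 4/3/1.
#'
#' @param background,subset paths to annotation tables.
#' @param universe path to the pathway-definition TSV.
#' @param mapping optional cluster-mapping path.
#' @param reactions_dir optional directory of per-pathway reaction TSVs.
#' @param out_dir output directory.
#' @param dialect an [annotation_dialect()] for both annotation tables.
#' @param max_e_value,min_identity annotation quality filters.
#' @param design,alpha,adjust enrichment-call settings.
#' @param targets pathway ids for the path-length-shell analysis; `NULL`
#'   picks the two highest-scoring pathways of the run.
#' @param shell_mode `"merged"` or `"max"` (see [distance_shells()]).
#' @param ttest_var `"welch"` or `"pooled"`.
#' @param motif_min_len,motif_min_enriched,motif_max_nonenriched motif
#'   thresholds.
#' @param motif_mode `"pmf"` or `"tail"` (see [motif_pvalue()]).
#' @param motif_significance reporting threshold for motifs.
#' @return a `run_config` list.
#' @export
run_config <- function(background, subset, universe, mapping = NULL,
                       reactions_dir = NULL, out_dir = "auxmet_out",
                       dialect = annotation_dialect(),
                       max_e_value = 1e-5, min_identity = NULL,
                       design = c("superset", "paired"), alpha = 1e-4,
                       adjust = c("none", "BH"), targets = NULL,
                       shell_mode = c("merged", "max"),
                       ttest_var = c("welch", "pooled"),
                       motif_min_len = 4L, motif_min_enriched = 3L,
                       motif_max_nonenriched = 1L,
                       motif_mode = c("pmf", "tail"),
                       motif_significance = 0.05) {
  cfg <- list(background = background, subset = subset, universe = universe,
              mapping = mapping, reactions_dir = reactions_dir,
              out_dir = out_dir, dialect = dialect,
              max_e_value = max_e_value, min_identity = min_identity,
              design = match.arg(design), alpha = alpha,
              adjust = match.arg(adjust), targets = targets,
              shell_mode = match.arg(shell_mode),
              ttest_var = match.arg(ttest_var),
              motif_min_len = motif_min_len,
              motif_min_enriched = motif_min_enriched,
              motif_max_nonenriched = motif_max_nonenriched,
              motif_mode = match.arg(motif_mode),
              motif_significance = motif_significance)
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[auxmet] stage %-12s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes annotation reading/expansion/filtering, KO enrichment
#' calling, pathway scoring, the global-metabolism-network analyses and
#' motif mining, writing every stage table under `config$out_dir`
#' together with a JSON summary and the fully resolved configuration.
#' Stage timings are logged to stderr; any stage error aborts with the
#' stage name.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$background, config$subset, config$universe,
              config$mapping, config$reactions_dir))
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_out <- config
  cfg_out$dialect <- unclass(config$dialect)
  jsonlite::write_json(unclass(cfg_out),
                       file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  annos <- .stage("annotations", {
    bg <- read_annotation_table(config$background, config$dialect, "background")
    sub <- read_annotation_table(config$subset, config$dialect, "viral")
    if (!is.null(config$mapping)) {
      mp <- read_cluster_mapping(config$mapping)
      bg <- expand_clusters(bg, mp)
      sub <- expand_clusters(sub, mp)
    }
    bg <- filter_annotations(bg, config$max_e_value, config$min_identity)
    sub <- filter_annotations(sub, config$max_e_value, config$min_identity)
    list(bg = bg, sub = sub)
  })

  calls <- .stage("enrichment", {
    cs <- count_kos(annos$sub)
    cb <- count_kos(annos$bg)
    res <- call_enriched_kos(cs, cb, design = config$design,
                             alpha = config$alpha)
    res <- adjust_pvalues(res, method = config$adjust)
    write_enrichment_table(res, file.path(config$out_dir, "ko_enrichment.tsv"))
    res
  })

  uni <- .stage("universe", load_pathway_definitions(config$universe))

  report <- .stage("pathways", {
    rep <- build_pathway_report(uni, calls)
    write_pathway_report(rep, file.path(config$out_dir, "pathway_report.tsv"))
    rep
  })

  netstats <- .stage("network", {
    net <- build_network(uni, enriched = report$pathway_id)
    export_network(net, file.path(config$out_dir, "network.graphml"), "graphml")
    export_network(net, file.path(config$out_dir, "network_edges.tsv"), "edgelist")
    out <- list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
                n_enriched = length(net$enriched))
    if (length(net$enriched) >= 1) {
      hub <- network_hub_enrichment(net)
      out$mhg <- list(statistic = hub$statistic, cutoff = hub$cutoff,
                      p_value = hub$p_value)
    }
    if (length(net$enriched) >= 1 &&
        length(net$enriched) < length(net$nodes)) {
      deg <- compare_degree_distributions(net)
      out$degree <- deg
    }
    targets <- config$targets
    if (is.null(targets) && nrow(report) >= 2)
      targets <- report$pathway_id[1:2]
    if (!is.null(targets) && all(targets %in% net$nodes)) {
      shells <- distance_shells(net, targets, mode = config$shell_mode)
      se <- shell_enrichment(shells, net$enriched)
      utils::write.table(se, file.path(config$out_dir, "shell_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$shells <- se
      dd <- tryCatch(compare_distance_distributions(shells, net$enriched,
                                                    var = config$ttest_var),
                     error = function(e) NULL)
      out$distance <- dd
    }
    out
  })

  motifs <- .stage("motifs", {
    if (is.null(config$reactions_dir)) {
      NULL
    } else {
      files <- list.files(config$reactions_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      enr <- enriched_kos(calls)$ko_id
      graphs <- lapply(files, read_reaction_graph, enriched_kos = enr)
      rep <- motif_report(graphs, significance = config$motif_significance,
                          min_len = config$motif_min_len,
                          min_enriched = config$motif_min_enriched,
                          max_nonenriched = config$motif_max_nonenriched,
                          mode = config$motif_mode)
      utils::write.table(rep, file.path(config$out_dir, "motifs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    }
  })

  summary <- list(
    n_background_annotations = nrow(annos$bg),
    n_subset_annotations = nrow(annos$sub),
    n_kos_tested = nrow(calls),
    n_kos_enriched = sum(calls$enriched),
    n_pathways = n_pathways(uni),
    n_pathways_scored = nrow(report),
    network = netstats[c("n_nodes", "n_edges", "n_enriched")],
    mhg = netstats$mhg, degree = netstats$degree,
    distance = netstats$distance,
    n_motifs = if (is.null(motifs)) NA_integer_ else nrow(motifs),
    n_motifs_significant = if (is.null(motifs)) NA_integer_
                           else sum(motifs$significant))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}
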