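#' Build the global metabolism network
#'
#' Pathway-level graph: every pathway is a node, and two pathways A and B
#' are joined by an (unweighted, undirected) edge when a product compound
#' of one is a substrate compound of the other, i.e. when a metabolite can
#' be passed between them.  Compounds on the optional exclusion list
#' (currency metabolites such as water or ATP) are removed from both
#' compound sets before intersecting; the default list is empty.
#'
#' @param universe a `pathway_universe` with substrate/product sets.
#' @param enriched character vector of enriched pathway ids (marked as a
#'   node attribute; must be a subset of the universe's pathways).
#' @param exclude_compounds compound ids ignored when intersecting.
#' @return a `metab_network`: list with `nodes` (pathway ids), `edges`
#'   (data.frame from/to with from < to), `enriched`.
#' @export
build_network <- function(universe, enriched = character(),
                          exclude_compounds = character()) {
  ids <- universe$pathway_id
  bad <- setdiff(enriched, ids)
  if (length(bad))
    stop("enriched pathway(s) not in universe: ", paste(bad, collapse = ", "))
  drop <- function(x) setdiff(x, exclude_compounds)
  subs <- lapply(universe$substrates[ids], drop)
  prods <- lapply(universe$products[ids], drop)
  # index compounds -> producing / consuming pathways, then join
  producers <- split(rep(ids, lengths(prods)), unlist(prods, use.names = FALSE))
  consumers <- split(rep(ids, lengths(subs)), unlist(subs, use.names = FALSE))
  shared <- intersect(names(producers), names(consumers))
  pairs <- do.call(rbind, lapply(shared, function(cmp)
    expand.grid(from = producers[[cmp]], to = consumers[[cmp]],
                stringsAsFactors = FALSE)))
  if (is.null(pairs)) pairs <- data.frame(from = character(), to = character())
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  a <- pmin(pairs$from, pairs$to)
  b <- pmax(pairs$from, pairs$to)
  edges <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  metab_network(ids, edges, enriched)
}

#' Construct a metabolism network directly
#'
#' @param nodes pathway ids.
#' @param edges data.frame with columns from, to (undirected; self-loops
#'   forbidden).
#' @param enriched subset of `nodes` flagged as viral-enriched.
#' @return a `metab_network`.
#' @export
metab_network <- function(nodes, edges = data.frame(from = character(),
                                                    to = character()),
                          enriched = character()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes))
      stop("edge endpoint(s) not in node set")
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (!all(enriched %in% nodes)) stop("enriched nodes must be a node subset")
  structure(list(nodes = nodes, edges = edges,
                 enriched = unique(as.character(enriched))),
            class = "metab_network")
}

#' @export
print.metab_network <- function(x, ...) {
  cat("global metabolism network:", length(x$nodes), "pathways,",
      nrow(x$edges), "edges,", length(x$enriched), "enriched\n")
  invisible(x)
}

#' Convert to / from igraph
#'
#' @param net a `metab_network`.
#' @return an undirected [igraph::graph] with a logical `enriched` node
#'   attribute.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::set_vertex_attr(g, "enriched",
                          value = net$nodes %in% net$enriched)
}

#' Node degrees
#'
#' @param net a `metab_network`.
#' @return named integer vector of degrees over all nodes.
#' @export
network_degrees <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$from, net$edges$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Rank pathways by connectivity
#'
#' Sorts pathways by descending degree (ties broken lexicographically by
#' pathway id, so the ranking is deterministic) and marks which are
#' enriched -- the ranked binary vector consumed by [mhg_test()].
#'
#' @param net a `metab_network`.
#' @return data.frame (pathway_id, degree, enriched) in rank order.
#' @export
rank_by_degree <- function(net) {
  d <- network_degrees(net)
  ord <- order(-d, names(d))
  data.frame(pathway_id = names(d)[ord], degree = unname(d[ord]),
             enriched = names(d)[ord] %in% net$enriched,
             stringsAsFactors = FALSE)
}

#' mHG over-representation of enriched pathways among hubs
#'
#' Ranks pathways by degree and tests, with the exact minimal
#' hypergeometric procedure, whether enriched pathways concentrate among
#' the most connected nodes.  Because degree ties materially affect a
#' ranked-list statistic and the tie order is otherwise arbitrary, a
#' validation mode averages the statistic and p-value over random
#' permutations of tied blocks.
#'
#' @param net a `metab_network` with at least one enriched node.
#' @param tie_policy `"lexicographic"` (deterministic default) or
#'   `"average"` (mean over `n_tie_perm` random tie orders).
#' @param n_tie_perm permutations for `"average"`.
#' @param seed RNG seed for `"average"` (required there for
#'   reproducibility).
#' @return for `"lexicographic"` an `mhg_result`; for `"average"` a list
#'   with mean statistic/p-value and the per-permutation values.
#' @export
network_hub_enrichment <- function(net, tie_policy = c("lexicographic", "average"),
                                   n_tie_perm = 100L, seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  ranked <- rank_by_degree(net)
  if (tie_policy == "lexicographic") return(mhg_test(ranked$enriched))
  d <- network_degrees(net)
  run_once <- function() {
    ord <- order(-d, sample.int(length(d)))
    mhg_test(names(d)[ord] %in% net$enriched)
  }
  res <- withr::with_seed(seed, replicate(n_tie_perm, run_once(),
                                          simplify = FALSE))
  list(mean_statistic = mean(vapply(res, `[[`, numeric(1), "statistic")),
       mean_p_value = mean(vapply(res, `[[`, numeric(1), "p_value")),
       draws = res)
}

#' Compare degree distributions of enriched vs other pathways
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, normal approximation
#' with tie correction, comparing node degrees of enriched and
#' non-enriched pathways.  The reported `U` counts pairwise wins of the
#' enriched group (R's `wilcox.test` `W` statistic for enriched vs other).
#'
#' @param net a `metab_network`; both groups must be non-empty.
#' @return list: mean_enriched, mean_other, U, p_value.
#' @export
compare_degree_distributions <- function(net) {
  d <- network_degrees(net)
  enr <- d[names(d) %in% net$enriched]
  oth <- d[!(names(d) %in% net$enriched)]
  if (!length(enr) || !length(oth))
    stop("both enriched and non-enriched groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(enr, oth, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(mean_enriched = mean(enr), mean_other = mean(oth),
       U = unname(wt$statistic), p_value = wt$p.value)
}

#' Path-length shells around target pathways
#'
#' Breadth-first distance from a merged target set (e.g. the purine and
#' pyrimidine metabolism pathways): every other pathway is assigned the
#' length of its shortest path to the *nearest* target.  With
#' `mode = "max"` a pathway is instead assigned the largest of its
#' per-target distances ("connected to both" read strictly).  Targets sit
#' at distance 0 and are excluded from shells; unreachable pathways are
#' reported separately and excluded from shell statistics.
#'
#' @param net a `metab_network`.
#' @param targets non-empty subset of the node set.
#' @param mode `"merged"` (default) or `"max"`.
#' @return a `distance_shells` object: list with `distances` (named
#'   vector over non-target nodes; `Inf` = unreachable), `shells` (list
#'   mapping distance to node ids), `unreachable`, `targets`, `mode`.
#' @export
distance_shells <- function(net, targets, mode = c("merged", "max")) {
  mode <- match.arg(mode)
  targets <- unique(as.character(targets))
  if (!length(targets) || !all(targets %in% net$nodes))
    stop("targets must be a non-empty subset of the node set")
  g <- as_igraph(net)
  dm <- igraph::distances(g, v = targets, to = igraph::V(g))
  colnames(dm) <- igraph::V(g)$name
  d <- if (mode == "merged") apply(dm, 2, min) else apply(dm, 2, max)
  d <- d[setdiff(net$nodes, targets)]
  reach <- is.finite(d)
  shells <- split(names(d)[reach], d[reach])
  structure(list(distances = d, shells = shells,
                 unreachable = names(d)[!reach],
                 targets = targets, mode = mode),
            class = "distance_shells")
}

#' Per-shell over-representation of enriched pathways
#'
#' For each path-length shell `d`, tests whether enriched pathways are
#' over-represented in that shell among all shell-assigned (reachable,
#' non-target) pathways, with the hypergeometric upper tail.
#'
#' @param shells a `distance_shells` result.
#' @param enriched character vector of enriched pathway ids.
#' @return data.frame (distance, n, k, K, N, p_value): shell size `n`,
#'   enriched in shell `k`, enriched among all assigned `K`, assigned
#'   total `N`.
#' @export
shell_enrichment <- function(shells, enriched) {
  assigned <- unlist(shells$shells, use.names = FALSE)
  N <- length(assigned)
  K <- sum(assigned %in% enriched)
  rows <- lapply(names(shells$shells), function(dist) {
    members <- shells$shells[[dist]]
    k <- sum(members %in% enriched)
    data.frame(distance = as.numeric(dist), n = length(members), k = k,
               K = K, N = N,
               p_value = hypergeom_upper_tail(k, K, length(members), N))
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    distance = numeric(), n = integer(), k = integer(), K = integer(),
    N = integer(), p_value = numeric()))))
  out[order(out$distance), , drop = FALSE]
}

#' Compare path-length distributions of enriched vs other pathways
#'
#' Two-sample t-test on per-pathway distances to the targets, asking
#' whether enriched pathways sit closer.  Welch's unequal-variance test is
#' the default; a pooled-variance variant is available, and `verbose`
#' reports both.
#'
#' @param shells a `distance_shells` result.
#' @param enriched character vector of enriched pathway ids.
#' @param var `"welch"` (default) or `"pooled"`.
#' @param verbose also return the non-default variant.
#' @return list: mean_enriched, mean_other, t, p_value (two-sided), plus
#'   `pooled`/`welch` sub-result when `verbose`.
#' @export
compare_distance_distributions <- function(shells, enriched,
                                           var = c("welch", "pooled"),
                                           verbose = FALSE) {
  var <- match.arg(var)
  d <- shells$distances[is.finite(shells$distances)]
  enr <- d[names(d) %in% enriched]
  oth <- d[!(names(d) %in% enriched)]
  if (length(enr) < 2L || length(oth) < 2L)
    stop("both groups need >= 2 shell-assigned members for a t-test")
  run <- function(equal) {
    tt <- stats::t.test(enr, oth, var.equal = equal)
    list(mean_enriched = mean(enr), mean_other = mean(oth),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
  }
  out <- run(var == "pooled")
  if (verbose)
    out[[if (var == "welch") "pooled" else "welch"]] <- run(var != "pooled")
  out
}

#' Export / import a metabolism network
#'
#' Lossless export of nodes, edges and the enriched-node attribute either
#' as an edge-list TSV (plus an isolated-node and enrichment side table)
#' or as GraphML (ready for Cytoscape-style tools); both round-trip
#' through [import_network()].
#'
#' @param net a `metab_network`.
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# nodes\tpathway_id\tenriched", con)
    if (length(net$nodes))
      writeLines(paste("N", net$nodes,
                       ifelse(net$nodes %in% net$enriched, 1L, 0L),
                       sep = "\t"), con)
    writeLines("# edges\tfrom\tto", con)
    if (nrow(net$edges))
      writeLines(paste("E", net$edges$from, net$edges$to, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nm <- igraph::V(g)$name
    el <- igraph::as_edgelist(g)
    enr <- nm[as.logical(igraph::V(g)$enriched)]
    return(metab_network(nm, data.frame(from = el[, 1], to = el[, 2],
                                        stringsAsFactors = FALSE), enr))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, character(1), 1)
  nd <- parts[tag == "N"]
  ed <- parts[tag == "E"]
  nodes <- vapply(nd, `[[`, character(1), 2)
  enr <- nodes[vapply(nd, `[[`, character(1), 3) == "1"]
  edges <- data.frame(from = vapply(ed, `[[`, character(1), 2),
                      to = vapply(ed, `[[`, character(1), 3),
                      stringsAsFactors = FALSE)
  metab_network(nodes, edges, enr)
}
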