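#' Construct a per-pathway reaction graph
#'
#' A reaction graph holds one directed edge per reaction: substrate
#' compound -> product compound, labelled by the ortholog groups promoting
#' the reaction.  A reaction is flagged enriched when at least one of its
#' KOs is in the supplied enriched set.
#'
#' @param reactions data.frame with columns `reaction_id`, `substrate`,
#'   `product`, `kos` (semicolon-separated KO ids or a list column).
#' @param enriched_kos character vector of enriched KO ids.
#' @param pathway_id id of the pathway the graph belongs to.
#' @param compounds optional declared compound set; reactions referencing
#'   an undeclared compound are an error.  Defaults to the compounds seen
#'   in `reactions`.
#' @return a `reaction_graph` object.
#' @export
reaction_graph <- function(reactions, enriched_kos = character(),
                           pathway_id = NA_character_, compounds = NULL) {
  if (is.character(reactions$kos))
    reactions$kos <- strsplit(reactions$kos, ";", fixed = TRUE)
  if (anyDuplicated(reactions$reaction_id)) stop("duplicate reaction_id")
  seen <- unique(c(reactions$substrate, reactions$product))
  if (is.null(compounds)) compounds <- seen
  bad <- setdiff(seen, compounds)
  if (length(bad))
    stop("reaction references undeclared compound(s): ",
         paste(bad, collapse = ", "))
  reactions$enriched <- vapply(reactions$kos, function(k)
    length(intersect(k, enriched_kos)) > 0L, logical(1))
  rownames(reactions) <- NULL
  structure(list(reactions = reactions, compounds = compounds,
                 pathway_id = pathway_id, enriched_kos = enriched_kos),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat("reaction graph", if (!is.na(x$pathway_id)) paste0("[", x$pathway_id, "]"),
      ":", length(x$compounds), "compounds,", nrow(x$reactions), "reactions (",
      sum(x$reactions$enriched), "enriched )\n")
  invisible(x)
}

#' Read / write a reaction graph TSV
#'
#' Format: columns `reaction_id`, `substrate`, `product`, `kos`
#' (semicolon-separated).  An optional `# pathway_id: xxx` comment line
#' carries the pathway id.
#'
#' @param path file path.
#' @param enriched_kos enriched KO set used to flag reactions.
#' @param pathway_id pathway id; if `NA`, taken from the comment line when
#'   present.
#' @return a `reaction_graph`.
#' @export
read_reaction_graph <- function(path, enriched_kos = character(),
                                pathway_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^# pathway_id:", lines, value = TRUE)
  if (is.na(pathway_id) && length(meta))
    pathway_id <- trimws(sub("^# pathway_id:", "", meta[[1]]))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, colClasses = "character", quote = "")
  need <- c("reaction_id", "substrate", "product", "kos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reaction graph file missing column(s): ", paste(miss, collapse = ", "))
  reaction_graph(df, enriched_kos, pathway_id)
}

#' @rdname read_reaction_graph
#' @param graph a `reaction_graph`.
#' @export
write_reaction_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(graph$pathway_id))
    writeLines(paste("# pathway_id:", graph$pathway_id), con)
  df <- graph$reactions
  df$kos <- vapply(df$kos, paste, character(1), collapse = ";")
  utils::write.table(df[, c("reaction_id", "substrate", "product", "kos")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a KGML pathway map as a reaction graph
#'
#' Minimal reader for KEGG Markup Language pathway files: `<reaction>`
#' elements supply substrate -> product edges, and the `<entry>` elements
#' of type `ortholog` supply the KO labels (entries and reactions are
#' joined on the reaction name).  Reversible reactions emit a single edge
#' in the stated direction; use `undirected = TRUE` in [find_motifs()] to
#' traverse them both ways.
#'
#' @param path KGML file path.
#' @param enriched_kos enriched KO set used to flag reactions.
#' @return a `reaction_graph`.
#' @export
read_kgml <- function(path, enriched_kos = character()) {
  doc <- xml2::read_xml(path)
  pid <- xml2::xml_attr(doc, "name")
  entries <- xml2::xml_find_all(doc, ".//entry[@type='ortholog']")
  rxn_of_entry <- xml2::xml_attr(entries, "reaction")
  kos_of_entry <- lapply(strsplit(xml2::xml_attr(entries, "name"), " +"),
                         function(x) sub("^ko:", "", x))
  ko_map <- list()
  for (i in seq_along(entries)) {
    if (is.na(rxn_of_entry[[i]])) next
    for (rn in strsplit(rxn_of_entry[[i]], " +")[[1]])
      ko_map[[rn]] <- union(ko_map[[rn]], kos_of_entry[[i]])
  }
  rxns <- xml2::xml_find_all(doc, ".//reaction")
  rows <- lapply(rxns, function(r) {
    name <- xml2::xml_attr(r, "name")
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(r, "./product"), "name")
    if (!length(subs) || !length(prods)) return(NULL)
    kos <- ko_map[[name]]
    if (is.null(kos)) kos <- character()
    df <- expand.grid(substrate = sub("^cpd:", "", subs),
                      product = sub("^cpd:", "", prods),
                      stringsAsFactors = FALSE)
    df$name <- name
    df$kos <- I(rep(list(kos), nrow(df)))
    df
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df))
    return(reaction_graph(data.frame(reaction_id = character(),
                                     substrate = character(),
                                     product = character(),
                                     kos = I(list())),
                          enriched_kos, pid))
  df$reaction_id <- make.unique(sub("^rn:", "", df$name), sep = "_")
  reaction_graph(df[, c("reaction_id", "substrate", "product", "kos")],
                 enriched_kos, pid)
}

# internal: orientation-aware neighbour lookup tables
.motif_index <- function(graph, undirected) {
  rx <- graph$reactions
  steps <- data.frame(idx = seq_len(nrow(rx)), from = rx$substrate,
                      to = rx$product, stringsAsFactors = FALSE)
  if (undirected && nrow(rx)) {
    rev <- data.frame(idx = steps$idx, from = steps$to, to = steps$from,
                      stringsAsFactors = FALSE)
    steps <- rbind(steps, rev[rev$from != rev$to, , drop = FALSE])
  }
  list(steps = steps, out = split(seq_len(nrow(steps)), steps$from),
       enriched = rx$enriched, ids = rx$reaction_id)
}

#' Mine metabolic motifs in a reaction graph
#'
#' A metabolic motif is a simple chain of consecutive reactions (the
#' product of each reaction is the substrate of the next) of length at
#' least `min_len`, in which at least `min_enriched` reactions are
#' promoted by enriched ortholog groups and at most `max_nonenriched` are
#' not.  By default only maximal motifs are reported: chains that cannot
#' be extended at either end without repeating a reaction or exceeding the
#' non-enriched budget.  Output order is deterministic (first reaction id,
#' then length).
#'
#' @param graph a `reaction_graph`.
#' @param min_len minimum chain length (default 4).
#' @param min_enriched minimum number of enriched reactions (default 3).
#' @param max_nonenriched maximum number of non-enriched reactions
#'   (default 1).
#' @param maximal report only inextensible chains (default `TRUE`); when
#'   `FALSE` every qualifying sub-chain is reported.
#' @param undirected also traverse reactions against their stated
#'   direction (for reversible-reaction analyses).
#' @return list of `motif` objects; each holds `reactions` (ids in chain
#'   order), `compounds` (visited compound sequence), `n_enriched`,
#'   `n_nonenriched`.
#' @export
find_motifs <- function(graph, min_len = 4L, min_enriched = 3L,
                        max_nonenriched = 1L, maximal = TRUE,
                        undirected = FALSE) {
  stopifnot(min_len >= min_enriched, min_enriched >= 0L, max_nonenriched >= 0L)
  ix <- .motif_index(graph, undirected)
  if (!nrow(ix$steps)) return(list())
  found <- list()
  emit <- function(chain_steps) {
    ridx <- ix$steps$idx[chain_steps]
    n_enr <- sum(ix$enriched[ridx])
    n_non <- length(ridx) - n_enr
    if (length(ridx) < min_len || n_enr < min_enriched) return()
    if (maximal && .extensible(chain_steps, ix, max_nonenriched)) return()
    found[[length(found) + 1L]] <<- structure(
      list(reactions = ix$ids[ridx],
           compounds = c(ix$steps$from[chain_steps[1]], ix$steps$to[chain_steps]),
           n_enriched = n_enr, n_nonenriched = n_non,
           step_rows = chain_steps),
      class = "motif")
  }
  dfs <- function(chain_steps, used, n_non) {
    emit(chain_steps)
    last <- chain_steps[length(chain_steps)]
    for (nxt in ix$out[[ix$steps$to[last]]]) {
      ridx <- ix$steps$idx[nxt]
      if (used[ridx]) next
      non2 <- n_non + !ix$enriched[ridx]
      if (non2 > max_nonenriched) next
      used[ridx] <- TRUE
      dfs(c(chain_steps, nxt), used, non2)
      used[ridx] <- FALSE
    }
  }
  used0 <- logical(nrow(graph$reactions))
  for (s in seq_len(nrow(ix$steps))) {
    ridx <- ix$steps$idx[s]
    n_non <- as.integer(!ix$enriched[ridx])
    if (n_non > max_nonenriched) next
    used <- used0
    used[ridx] <- TRUE
    dfs(s, used, n_non)
  }
  # deterministic order, dedup chains reachable from several start rows
  key <- vapply(found, function(m) paste(m$step_rows, collapse = ","), character(1))
  found <- found[!duplicated(key)]
  ord <- order(vapply(found, function(m) m$reactions[[1]], character(1)),
               lengths(lapply(found, `[[`, "reactions")),
               vapply(found, function(m) paste(m$reactions, collapse = ";"),
                      character(1)))
  found[ord]
}

# can the chain be prepended/appended with any unused reaction without
# busting the non-enriched budget?  (length and enriched count only grow
# under extension, so these are the only constraints that can fail)
.extensible <- function(chain_steps, ix, max_nonenriched) {
  ridx <- ix$steps$idx[chain_steps]
  n_non <- sum(!ix$enriched[ridx])
  head_cmp <- ix$steps$from[chain_steps[1]]
  tail_cmp <- ix$steps$to[chain_steps[length(chain_steps)]]
  cand_after <- ix$out[[tail_cmp]]
  cand_before <- which(ix$steps$to == head_cmp)
  for (s in c(cand_after, cand_before)) {
    r <- ix$steps$idx[s]
    if (r %in% ridx) next
    if ((n_non + !ix$enriched[r]) <= max_nonenriched) return(TRUE)
  }
  FALSE
}

#' Binomial significance of a metabolic motif
#'
#' Scores a motif against the chance of assembling such a chain at random
#' within its pathway.  Let `p` be the fraction of the pathway's reactions
#' promoted by at least one enriched KO.  For each transition into a
#' compound `c` (every reaction after the first), `n` counts the reactions
#' incident to `c` excluding the previous motif reaction and `y` counts
#' how many of those are enriched; the transition term is the binomial
#' point mass `C(n, y) p^y (1-p)^(n-y)` (or the upper tail `P(Y >= y)`
#' with `mode = "tail"`).  The motif p-value is the product of its
#' transition terms.  With `include_first = TRUE` the first reaction also
#' contributes a term, with `n` = all reactions incident to its substrate
#' compound.
#'
#' @param motif a `motif` from [find_motifs()].
#' @param graph the `reaction_graph` it was mined from (must have >= 1
#'   reaction).
#' @param mode `"pmf"` (point mass, default) or `"tail"`.
#' @param include_first score the first reaction too (default `FALSE`).
#' @return the motif p-value, with attribute `"terms"`: a data.frame of
#'   per-step (compound, n, y, term).
#' @export
motif_pvalue <- function(motif, graph, mode = c("pmf", "tail"),
                         include_first = FALSE) {
  mode <- match.arg(mode)
  rx <- graph$reactions
  if (!nrow(rx)) stop("pathway has no reactions")
  p <- mean(rx$enriched)
  incident <- function(cmp) which(rx$substrate == cmp | rx$product == cmp)
  pos <- match(motif$reactions, rx$reaction_id)
  if (anyNA(pos)) stop("motif reaction(s) not present in graph")
  steps <- seq_along(pos)[-1]
  term_of <- function(n, y) {
    if (mode == "pmf") stats::dbinom(y, n, p)
    else stats::pbinom(y - 1, n, p, lower.tail = FALSE)
  }
  rows <- lapply(steps, function(i) {
    cmp <- motif$compounds[[i]]           # compound entered by reaction i
    inc <- setdiff(incident(cmp), pos[i - 1])
    n <- length(inc)
    y <- sum(rx$enriched[inc])
    data.frame(compound = cmp, n = n, y = y, term = term_of(n, y))
  })
  if (include_first) {
    cmp <- motif$compounds[[1]]
    inc <- incident(cmp)
    rows <- c(list(data.frame(compound = cmp, n = length(inc),
                              y = sum(rx$enriched[inc]),
                              term = term_of(length(inc),
                                             sum(rx$enriched[inc])))),
              rows)
  }
  terms <- do.call(rbind, rows)
  structure(prod(terms$term), terms = terms)
}

#' Motif report over one or more reaction graphs
#'
#' Mines and scores motifs, marking those below the significance
#' threshold; all motifs are emitted regardless of the flag.
#'
#' @param graphs a `reaction_graph` or list of them.
#' @param significance reporting threshold on the motif p-value
#'   (default 0.05; marks rows, does not drop them).
#' @param ... passed to [find_motifs()] and [motif_pvalue()] (`min_len`,
#'   `min_enriched`, `max_nonenriched`, `mode`, ...).
#' @return data.frame (pathway_id, reactions, length, n_enriched,
#'   p_value, significant).
#' @export
motif_report <- function(graphs, significance = 0.05, ...) {
  if (inherits(graphs, "reaction_graph")) graphs <- list(graphs)
  dots <- list(...)
  find_args <- dots[names(dots) %in% names(formals(find_motifs))]
  pv_args <- dots[names(dots) %in% c("mode", "include_first")]
  rows <- lapply(graphs, function(g) {
    motifs <- do.call(find_motifs, c(list(g), find_args))
    if (!length(motifs)) return(NULL)
    do.call(rbind, lapply(motifs, function(m) {
      pv <- do.call(motif_pvalue, c(list(m, g), pv_args))
      data.frame(pathway_id = g$pathway_id,
                 reactions = paste(m$reactions, collapse = ";"),
                 length = length(m$reactions), n_enriched = m$n_enriched,
                 p_value = as.numeric(pv), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    pathway_id = character(), reactions = character(), length = integer(),
    n_enriched = integer(), p_value = numeric(), stringsAsFactors = FALSE))))
  out$significant <- out$p_value < significance
  rownames(out) <- NULL
  out
}
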