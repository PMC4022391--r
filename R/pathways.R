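#' Construct a pathway universe
#'
#' A pathway universe holds, per pathway, the member ortholog groups and the
#' substrate / product compound sets used later to build the global
#' metabolism network.  A reverse index from KO to the pathways containing
#' it is built on construction.
#'
#' @param pathway_id,name character vectors, one entry per pathway.
#' @param members list of character vectors of member KO ids (>= 1 each).
#' @param substrates,products lists of compound-id character vectors.
#' @return a `pathway_universe` object.
#' @export
pathway_universe <- function(pathway_id, name, members,
                             substrates = NULL, products = NULL) {
  pathway_id <- as.character(pathway_id)
  if (anyDuplicated(pathway_id))
    stop("duplicate pathway_id: ",
         paste(unique(pathway_id[duplicated(pathway_id)]), collapse = ", "))
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) < 1L))
    stop("every pathway needs >= 1 member KO")
  empty <- rep(list(character()), length(pathway_id))
  if (is.null(substrates)) substrates <- empty
  if (is.null(products)) products <- empty
  substrates <- lapply(substrates, function(x) unique(as.character(x)))
  products <- lapply(products, function(x) unique(as.character(x)))
  names(members) <- names(substrates) <- names(products) <- pathway_id
  rev_idx <- split(rep(pathway_id, lengths(members)),
                   unlist(members, use.names = FALSE))
  structure(list(pathway_id = pathway_id,
                 name = stats::setNames(as.character(name), pathway_id),
                 members = members, substrates = substrates,
                 products = products, ko_index = rev_idx),
            class = "pathway_universe")
}

#' @export
print.pathway_universe <- function(x, ...) {
  cat("pathway universe:", length(x$pathway_id), "pathways,",
      length(x$ko_index), "distinct KOs,",
      length(unique(unlist(c(x$substrates, x$products)))), "compounds\n")
  invisible(x)
}

#' @rdname pathway_universe
#' @param universe a `pathway_universe`.
#' @export
n_pathways <- function(universe) length(universe$pathway_id)

#' Pathways containing a KO
#'
#' @param universe a `pathway_universe`.
#' @param ko_id KO identifier(s).
#' @return character vector of pathway ids (union over the given KOs).
#' @export
pathways_of_ko <- function(universe, ko_id) {
  unique(unlist(universe$ko_index[ko_id], use.names = FALSE))
}

#' Load / write pathway definitions
#'
#' The pathway-universe interchange format is a TSV with columns
#' `pathway_id`, `name`, `member_kos`, `substrates`, `products`, where the
#' three set-valued columns are semicolon-separated.
#'
#' @param path file path.
#' @return a `pathway_universe`.
#' @export
load_pathway_definitions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("pathway_id", "name", "member_kos", "substrates", "products")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pathway definition file missing column(s): ", paste(miss, collapse = ", "))
  split_set <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(s) s[nzchar(s)])
  members <- split_set(df$member_kos)
  if (any(lengths(members) < 1L))
    stop("pathway(s) with empty member KO list: ",
         paste(df$pathway_id[lengths(members) < 1L], collapse = ", "))
  pathway_universe(df$pathway_id, df$name, members,
                   split_set(df$substrates), split_set(df$products))
}

#' @rdname load_pathway_definitions
#' @param universe a `pathway_universe`.
#' @export
write_pathway_definitions <- function(universe, path) {
  join <- function(l) vapply(l, paste, character(1), collapse = ";")
  df <- data.frame(pathway_id = universe$pathway_id,
                   name = unname(universe$name),
                   member_kos = join(universe$members),
                   substrates = join(universe$substrates),
                   products = join(universe$products),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway enrichment score
#'
#' Scores a pathway by its enriched member ortholog groups:
#' \deqn{ES = N \cdot \frac{\sum_{n=1}^{N} -\log_{10} P_n}{T}}
#' where `N` is the number of enriched member KOs, `P_n` their enrichment
#' p-values and `T` the total number of KOs in the pathway.  The score
#' rewards pathways whose enriched members are both numerous relative to
#' the pathway size and individually strongly enriched.
#'
#' @param p_values numeric vector of enrichment p-values of the pathway's
#'   enriched member KOs (length `N`); each must lie in (0, 1\].
#' @param T_total total number of member KOs in the pathway (>= 1).
#' @param p_floor p-values below this floor are raised to it so the score
#'   stays finite; a zero p-value is a hard error with guidance to floor
#'   upstream.
#' @return the non-negative enrichment score; 0 iff `N = 0`.
#' @export
pathway_enrichment_score <- function(p_values, T_total, p_floor = 1e-300) {
  stopifnot(T_total >= 1)
  if (!length(p_values)) return(0)
  if (any(p_values <= 0))
    stop("p-value of 0 gives an infinite enrichment score; ",
         "floor p-values (see p_floor) before scoring")
  if (any(p_values > 1)) stop("p-values must lie in (0, 1]")
  p <- pmax(p_values, p_floor)
  N <- length(p)
  N * sum(-log10(p)) / T_total
}

#' Build the pathway enrichment report
#'
#' Maps enriched KOs onto the pathway universe and scores every pathway
#' containing at least one enriched member with
#' [pathway_enrichment_score()].  Pathways with no enriched member are
#' omitted.  Enriched KOs found in no pathway raise a warning (they fall
#' outside the metabolic universe), not an error.
#'
#' @param universe a `pathway_universe`.
#' @param calls a `ko_enrichment` table (or any data.frame with `ko_id`,
#'   `p_value`, `enriched` columns).
#' @param p_floor forwarded to [pathway_enrichment_score()].
#' @return a `pathway_report` data.frame with columns pathway_id, name, es,
#'   n_enriched, n_total and kos (semicolon-joined sorted enriched KO ids),
#'   sorted by descending score (ties by pathway_id).
#' @export
build_pathway_report <- function(universe, calls, p_floor = 1e-300) {
  enr <- calls[calls$enriched, c("ko_id", "p_value"), drop = FALSE]
  orphans <- setdiff(enr$ko_id, names(universe$ko_index))
  if (length(orphans))
    warning("enriched KO(s) absent from every pathway: ",
            paste(orphans, collapse = ", "))
  pvals <- stats::setNames(enr$p_value, enr$ko_id)
  rows <- lapply(universe$pathway_id, function(pid) {
    hit <- sort(intersect(universe$members[[pid]], enr$ko_id))
    if (!length(hit)) return(NULL)
    T_total <- length(universe$members[[pid]])
    data.frame(pathway_id = pid, name = unname(universe$name[pid]),
               es = pathway_enrichment_score(unname(pvals[hit]), T_total,
                                             p_floor = p_floor),
               n_enriched = length(hit), n_total = T_total,
               kos = paste(hit, collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    pathway_id = character(), name = character(), es = numeric(),
    n_enriched = integer(), n_total = integer(), kos = character(),
    stringsAsFactors = FALSE))))
  out <- out[order(-out$es, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pathway_report", "data.frame"))
}

#' Back-solve per-KO enrichment weights from a pathway report
#'
#' The enrichment score is additive in the per-KO weights
#' `w = -log10 P`: every report row constrains the weight sum of its
#' enriched KOs via `sum(w) = ES * T / N`.  Because enriched KOs are
#' modular (one KO scores in several pathways with the same weight), rows
#' with a single enriched KO pin that KO's weight, and rows where all but
#' one KO is already solved pin the remainder.  This function propagates
#' those constraints to convergence and is the basis of score-consistency
#' checks across a published report.
#'
#' @param report a `pathway_report`-shaped data.frame (columns `es`,
#'   `n_enriched`, `n_total`, `kos`; `kos` semicolon-separated).
#' @param exclude pathway ids whose rows are ignored (e.g. a row being
#'   predicted, or a row known to be internally inconsistent).
#' @return list with `weights` (named numeric, solved KO weights) and
#'   `row_sums` (named numeric, `ES * T / N` per retained row).
#' @export
solve_ko_weights <- function(report, exclude = character()) {
  rows <- report[!(report$pathway_id %in% exclude), , drop = FALSE]
  kos <- strsplit(rows$kos, ";", fixed = TRUE)
  row_sums <- stats::setNames(rows$es * rows$n_total / rows$n_enriched,
                              rows$pathway_id)
  weights <- numeric(0)
  repeat {
    progressed <- FALSE
    for (i in seq_along(kos)) {
      unknown <- setdiff(kos[[i]], names(weights))
      if (length(unknown) == 1L) {
        w <- row_sums[[i]] - sum(weights[setdiff(kos[[i]], unknown)])
        weights[unknown] <- w
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  list(weights = weights, row_sums = row_sums)
}

#' Predict a pathway's enrichment score from solved KO weights
#'
#' Given per-KO weights (see [solve_ko_weights()]), predicts the score a
#' pathway would receive if exactly those KOs were enriched: the weights
#' are converted back to p-values `10^-w` and passed through
#' [pathway_enrichment_score()], so the prediction exercises the same
#' scoring path as the pipeline.
#'
#' @param weights numeric vector of per-KO weights `-log10 P` (names
#'   optional); alternatively supply `weight_sum`.
#' @param T_total pathway size.
#' @param weight_sum total weight when only the sum is identifiable; split
#'   evenly over `n` pseudo-KOs (the score depends only on the sum and on
#'   `n`).
#' @param n number of enriched KOs when using `weight_sum`.
#' @return the predicted enrichment score.
#' @export
predict_pathway_score <- function(weights = NULL, T_total, weight_sum = NULL,
                                  n = length(weights)) {
  if (is.null(weights)) {
    stopifnot(!is.null(weight_sum), n >= 1)
    weights <- rep(weight_sum / n, n)
  }
  pathway_enrichment_score(10^(-weights), T_total)
}

#' Score-consistency check across a pathway report
#'
#' A pathway report over-determines the per-KO weights `w = -log10 P`
#' whenever KOs recur across pathways (modularity): each row constrains
#' the weight sum of its enriched KOs through `sum(w) = ES * T / N`.
#' This function predicts one row's score purely from *other* rows: the
#' source rows form a linear system `A w = b`, solved by minimum-norm
#' least squares (SVD); the target's weight sum is the inner product of
#' its KO-indicator with the solution, which is well-defined exactly when
#' that indicator lies in the row space of `A` -- otherwise the target is
#' not identifiable from the chosen sources and an error is raised.  The
#' predicted weight sum is then pushed through the same scoring path as
#' the pipeline ([pathway_enrichment_score()] on back-converted
#' p-values).
#'
#' @param report a `pathway_report`-shaped data.frame.
#' @param target_id pathway id of the row to predict.
#' @param source_ids pathway ids of the rows to solve from (must not
#'   include the target).
#' @return list with `predicted`, `printed` (the report's score for the
#'   target) and `relative_error`.
#' @export
check_score_consistency <- function(report, target_id, source_ids) {
  if (target_id %in% source_ids)
    stop("source rows must not include the target row")
  t_row <- report[report$pathway_id == target_id, , drop = FALSE]
  src <- report[report$pathway_id %in% source_ids, , drop = FALSE]
  if (nrow(t_row) != 1L || nrow(src) != length(unique(source_ids)))
    stop("target or source pathway id(s) not found in report")
  kos_list <- strsplit(src$kos, ";", fixed = TRUE)
  target_kos <- strsplit(t_row$kos, ";", fixed = TRUE)[[1]]
  all_kos <- sort(unique(c(unlist(kos_list), target_kos)))
  A <- t(vapply(kos_list, function(k) as.numeric(all_kos %in% k),
                numeric(length(all_kos))))
  b <- src$es * src$n_total / src$n_enriched
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  w <- V %*% ((t(U) %*% b) / sv$d[pos])
  cvec <- as.numeric(all_kos %in% target_kos)
  if (max(abs(V %*% (t(V) %*% cvec) - cvec)) > 1e-8)
    stop("target '", target_id,
         "' is not identifiable from the given source rows")
  predicted <- predict_pathway_score(weight_sum = sum(cvec * w),
                                     T_total = t_row$n_total,
                                     n = t_row$n_enriched)
  list(predicted = predicted, printed = t_row$es,
       relative_error = abs(predicted - t_row$es) / t_row$es)
}

#' Published VirMic pathway enrichment table
#'
#' The pathway enrichment scores reported for the VirMic viral subset of
#' the Global Ocean Survey metagenome (hypergeometric design, threshold
#' P < 1e-4), shipped as plain text.  Used by the score-consistency
#' validation suite: the table over-determines the per-KO weights, so
#' scores back-solved from some rows must reproduce the printed scores of
#' others.
#'
#' @return a data.frame with columns pathway_id, name, es, n_enriched,
#'   n_total, kos.
#' @export
virmic_pathway_report <- function() {
  path <- system.file("extdata", "virmic_pathway_enrichment.tsv",
                      package = "auxmet", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = c("character", "character", "numeric",
                                         "integer", "integer", "character"),
                          comment.char = "")
  structure(df, class = c("pathway_report", "data.frame"))
}

#' Write a pathway report as TSV
#'
#' @param report a `pathway_report`.
#' @param path output path.
#' @export
write_pathway_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
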