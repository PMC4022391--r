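#' Hypergeometric upper-tail probability
#'
#' Over-representation test for a subset-of-superset design: the population
#' holds `N` ortholog-group annotations of which `K` belong to the KO under
#' test; `n` annotations fall in the viral subset, `k` of them carry the KO.
#' Returns `P(X >= k)` for X hypergeometric, evaluated in log space via
#' [stats::phyper()] so that large metagenome-scale counts stay accurate.
#'
#' @param k successes observed in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return upper-tail probability in \[0, 1\] (vectorised).
#' @seealso [hypergeom_point_mass()] for the point probability
#'   `P(X = k)`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  .check_hyper_bounds(k, K, n, N)
  # P(X >= k) = 1 - P(X <= k - 1); lower.tail=FALSE keeps precision for
  # small tails
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Hypergeometric point mass
#'
#' The probability `P(X = k)` of seeing exactly `k` subset annotations for a
#' KO with `K` population annotations, under the same sampling model as
#' [hypergeom_upper_tail()].
#'
#' @inheritParams hypergeom_upper_tail
#' @return `P(X = k)` (vectorised).
#' @export
hypergeom_point_mass <- function(k, K, n, N) {
  .check_hyper_bounds(k, K, n, N)
  stats::dhyper(k, K, N - K, n)
}

.check_hyper_bounds <- function(k, K, n, N) {
  ok <- k >= 0 & k <= pmin(K, n) & K <= N & n <= N & k >= (n - (N - K))
  # k < n - (N - K) is impossible but not an argument error; treat args
  # violating the declared preconditions as hard errors
  if (any(k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  invisible(ok)
}

#' One-sided Fisher exact test (greater in sample 1)
#'
#' Two-sample design for paired virome/microbiome metagenomes: `k1` of `n1`
#' virome annotations versus `k2` of `n2` microbiome annotations carry the
#' KO.  The p-value is the probability, with all margins of the 2x2 table
#' `[[k1, n1-k1], [k2, n2-k2]]` fixed, of a first-cell count at least as
#' large as observed -- i.e. the hypergeometric upper tail with population
#' `n1 + n2`, successes `k1 + k2` and draw `n1` (the conditional-margins
#' identity).
#'
#' @param k1,n1 KO count and total annotations in the test sample (virome).
#' @param k2,n2 KO count and total annotations in the reference sample.
#' @return one-sided p-value (vectorised).
#' @export
fisher_exact_greater <- function(k1, n1, k2, n2) {
  if (any(k1 < 0 | k1 > n1 | k2 < 0 | k2 > n2 | (n1 + n2) <= 0))
    stop("fisher bounds violated: need 0 <= k1 <= n1, 0 <= k2 <= n2, n1 + n2 > 0")
  hypergeom_upper_tail(k1, k1 + k2, n1, n1 + n2)
}

#' Call enriched ortholog groups
#'
#' Tests every KO present in the viral set for over-representation.  In the
#' `"superset"` design the viral set is a literal subset of the reference
#' (the reads were drawn from it) and the hypergeometric upper tail applies;
#' in the `"paired"` design the two sets are independent samples and the
#' one-sided Fisher exact test applies.  A KO is called enriched when its
#' raw p-value falls below `alpha` (default `1e-4`); no multiple-testing
#' correction is applied unless requested via [adjust_pvalues()].
#'
#' @param subset `ko_counts` for the viral set (subset or virome).
#' @param reference `ko_counts` for the background superset or the paired
#'   microbiome.
#' @param design `"superset"` or `"paired"`.
#' @param alpha enrichment threshold on the p-value (strict `<`).
#' @return a `ko_enrichment` data.frame with columns ko_id, k, K, n, N,
#'   p_value, enriched, sorted by ascending p-value (ties by ko_id);
#'   attributes `alpha` and `design`.
#' @export
call_enriched_kos <- function(subset, reference,
                              design = c("superset", "paired"),
                              alpha = 1e-4) {
  design <- match.arg(design)
  stopifnot(alpha >= 0)
  n <- ko_total(subset)
  N <- ko_total(reference)
  ref <- stats::setNames(reference$count, reference$ko_id)
  k <- subset$count
  K <- ref[subset$ko_id]
  K[is.na(K)] <- 0L
  if (design == "superset") {
    if (n > N)
      stop("superset design: subset total (", n, ") exceeds reference total (", N, ")")
    bad <- k > K
    if (any(bad))
      stop("superset design violated: subset count exceeds reference count for KO(s) ",
           paste(subset$ko_id[bad], collapse = ", "))
    p <- hypergeom_upper_tail(k, K, n, N)
    res <- data.frame(ko_id = subset$ko_id, k = k, K = as.integer(K),
                      n = n, N = N, p_value = p, stringsAsFactors = FALSE)
  } else {
    p <- fisher_exact_greater(k, n, K, N)
    res <- data.frame(ko_id = subset$ko_id, k = k, K = as.integer(K),
                      n = n, N = N, p_value = p, stringsAsFactors = FALSE)
  }
  res$enriched <- res$p_value < alpha
  res <- res[order(res$p_value, res$ko_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, alpha = alpha, design = design,
            class = c("ko_enrichment", "data.frame"))
}

#' Optional multiple-testing adjustment
#'
#' The pipeline's default enrichment call uses the raw p-value threshold;
#' Benjamini-Hochberg adjustment is offered behind this function for users
#' who prefer FDR control.  With `method = "none"` the input is returned
#' unchanged.
#'
#' @param calls a `ko_enrichment` table from [call_enriched_kos()].
#' @param method `"none"` or `"BH"`.
#' @param alpha threshold re-applied to the adjusted p-values (defaults to
#'   the alpha recorded on `calls`).
#' @return a `ko_enrichment` table; under BH an extra `p_adjusted` column
#'   drives the `enriched` flags.
#' @export
adjust_pvalues <- function(calls, method = c("none", "BH"), alpha = NULL) {
  method <- match.arg(method)
  if (method == "none") return(calls)
  if (is.null(alpha)) alpha <- attr(calls, "alpha")
  calls$p_adjusted <- stats::p.adjust(calls$p_value, method = "BH")
  calls$enriched <- calls$p_adjusted < alpha
  attr(calls, "adjust_method") <- method
  calls
}

#' Extract the enriched KO list
#'
#' @param calls a `ko_enrichment` table.
#' @return data.frame (ko_id, p_value) of KOs flagged enriched, sorted by
#'   ascending p-value.
#' @export
enriched_kos <- function(calls) {
  out <- calls[calls$enriched, c("ko_id", "p_value"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param calls a `ko_enrichment` table.
#' @param path output path.
#' @export
write_enrichment_table <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
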