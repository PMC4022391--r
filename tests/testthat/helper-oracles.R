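# Independent brute-force oracles used to freeze expected values.  These
# deliberately share no code with the package implementations they check.

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
enum_hyper_tail <- function(k, K, n, N) {
  items <- c(rep(1L, K), rep(0L, N - K))   # 1 = success
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(items[idx]) >= k)
  mean(hits)
}

# mHG statistic recomputed from first principles (sum of point masses)
enum_mhg_stat <- function(v) {
  n <- length(v); B <- sum(v); b <- cumsum(v)
  tails <- vapply(seq_len(n), function(l) {
    ks <- b[l]:min(l, B)
    sum(choose(B, ks) * choose(n - B, l - ks)) / choose(n, l)
  }, numeric(1))
  min(tails)
}

# exhaustive mHG p-value: fraction of all C(n, B) arrangements whose
# statistic is <= the observed one
enum_mhg_pvalue <- function(v) {
  n <- length(v); B <- sum(v)
  s_obs <- enum_mhg_stat(v)
  pos <- utils::combn(n, B)
  stats <- apply(pos, 2, function(p) {
    u <- integer(n); u[p] <- 1L
    enum_mhg_stat(u)
  })
  mean(stats <= s_obs * (1 + 1e-9) + 1e-15)
}

# compound-sharing edges by O(n^2) pairwise check
brute_force_edges <- function(universe) {
  ids <- universe$pathway_id
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- ids[i]; b <- ids[j]
    if (length(intersect(universe$products[[a]], universe$substrates[[b]])) ||
        length(intersect(universe$products[[b]], universe$substrates[[a]])))
      out[[length(out) + 1L]] <- c(a, b)
  }
  if (!length(out)) return(data.frame(from = character(), to = character()))
  m <- do.call(rbind, out)
  df <- data.frame(from = pmin(m[, 1], m[, 2]), to = pmax(m[, 1], m[, 2]),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df[order(df$from, df$to), ]
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
floyd_warshall <- function(net) {
  n <- length(net$nodes)
  d <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# exhaustive motif enumeration: depth-first over all simple directed
# reaction chains, then constraint + maximality filtering on the full set
enum_motifs <- function(graph, min_len = 4, min_enriched = 3,
                        max_nonenriched = 1, undirected = FALSE) {
  rx <- graph$reactions
  n <- nrow(rx)
  if (!n) return(list())
  ori <- data.frame(idx = seq_len(n), from = rx$substrate, to = rx$product,
                    stringsAsFactors = FALSE)
  if (undirected) {
    rev <- data.frame(idx = seq_len(n), from = rx$product, to = rx$substrate,
                      stringsAsFactors = FALSE)
    ori <- rbind(ori, rev[rev$from != rev$to, ])
  }
  chains <- list()
  grow <- function(rows) {
    chains[[length(chains) + 1L]] <<- rows
    last_to <- ori$to[rows[length(rows)]]
    for (s in seq_len(nrow(ori)))
      if (ori$from[s] == last_to && !(ori$idx[s] %in% ori$idx[rows]))
        grow(c(rows, s))
  }
  for (s in seq_len(nrow(ori))) grow(s)
  ok <- Filter(function(rows) {
    enr <- rx$enriched[ori$idx[rows]]
    length(rows) >= min_len && sum(enr) >= min_enriched &&
      sum(!enr) <= max_nonenriched
  }, chains)
  budget_ok <- Filter(function(rows) {
    sum(!rx$enriched[ori$idx[rows]]) <= max_nonenriched
  }, chains)
  key <- function(rows) paste(rows, collapse = ",")
  budget_keys <- vapply(budget_ok, key, character(1))
  maximal <- Filter(function(rows) {
    # maximal iff no budget-respecting chain extends it by one step
    !any(vapply(budget_ok, function(other)
      length(other) == length(rows) + 1L &&
        (key(other[seq_along(rows)]) == key(rows) ||
         key(other[-1]) == key(rows)), logical(1)))
  }, ok)
  lapply(maximal, function(rows)
    list(reactions = rx$reaction_id[ori$idx[rows]],
         n_enriched = sum(rx$enriched[ori$idx[rows]])))
}

# small random reaction graph for motif oracle sweeps
random_reaction_graph <- function(n_rx, n_cmp = max(3, ceiling(n_rx * 0.7)),
                                  p_enriched = 0.6) {
  cmp <- sprintf("c%02d", seq_len(n_cmp))
  sub <- sample(cmp, n_rx, replace = TRUE)
  prod <- sample(cmp, n_rx, replace = TRUE)
  shift <- sub == prod
  prod[shift] <- cmp[(match(sub[shift], cmp) %% n_cmp) + 1L]
  kos <- sprintf("K%03d", seq_len(n_rx))
  enr <- kos[stats::runif(n_rx) < p_enriched]
  reaction_graph(data.frame(reaction_id = sprintf("r%02d", seq_len(n_rx)),
                            substrate = sub, product = prod, kos = kos,
                            stringsAsFactors = FALSE),
                 enriched_kos = enr, pathway_id = "rand")
}

# random small pathway universe for network oracle sweeps
random_universe <- function(n_pathways = 20, n_compounds = 12,
                            n_kos = 40, sets = 3) {
  kos <- sprintf("K%03d", seq_len(n_kos))
  cmp <- sprintf("c%02d", seq_len(n_compounds))
  ids <- sprintf("p%02d", seq_len(n_pathways))
  pathway_universe(ids, paste("pathway", ids),
                   lapply(seq_len(n_pathways), function(i) sample(kos, sets)),
                   lapply(seq_len(n_pathways), function(i) sample(cmp, sets)),
                   lapply(seq_len(n_pathways), function(i) sample(cmp, sets)))
}

# tiny fixture: linear 4-reaction chain, reactions 1, 2, 4 enriched
linear_chain_graph <- function() {
  reaction_graph(
    data.frame(reaction_id = paste0("r", 1:4),
               substrate = paste0("c", 1:4), product = paste0("c", 2:5),
               kos = c("K1", "K2", "K3", "K4"), stringsAsFactors = FALSE),
    enriched_kos = c("K1", "K2", "K4"), pathway_id = "chain")
}

small_synth_config <- function(seed = 1L, n_planted = 4L, ...) {
  synth_config(seed = seed, n_pathways = 12L, ko_pool = 60L,
               kos_per_pathway = c(3L, 8L), compound_pool = 30L,
               n_background_reads = 20000L, n_subset_reads = 500L,
               n_planted = n_planted, ...)
}
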