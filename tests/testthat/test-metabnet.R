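test_that("compound-sharing edges follow the product/substrate rule", {
  u <- pathway_universe(c("A", "B", "C"), c("a", "b", "c"),
                        list("K1", "K2", "K3"),
                        substrates = list("s1", "c1", "s3"),
                        products = list("c1", "p2", "p3"))
  net <- build_network(u)
  expect_equal(net$edges, data.frame(from = "A", to = "B"))

  # disjoint compound sets give no edges
  u2 <- pathway_universe(c("A", "B"), c("a", "b"), list("K1", "K2"),
                         substrates = list("s1", "s2"),
                         products = list("p1", "p2"))
  expect_equal(nrow(build_network(u2)$edges), 0L)

  # a compound on the exclusion list cannot create an edge
  expect_equal(nrow(build_network(u, exclude_compounds = "c1")$edges), 0L)
})

test_that("random universes match the brute-force pairwise edge check", {
  withr::with_seed(41, {
    for (i in 1:10) {
      u <- random_universe(n_pathways = 20, n_compounds = 10, sets = 3)
      net <- build_network(u)
      expect_equal(net$edges, brute_force_edges(u), ignore_attr = TRUE)
      # degree sum identity
      expect_equal(sum(network_degrees(net)), 2L * nrow(net$edges))
    }
  })
})

test_that("degree ranking is deterministic with lexicographic tie-break", {
  star <- metab_network(c("hub", paste0("leaf", 1:4)),
                        data.frame(from = "hub", to = paste0("leaf", 1:4)),
                        enriched = "hub")
  rk <- rank_by_degree(star)
  expect_equal(rk$pathway_id[1], "hub")
  expect_equal(rk$degree[1], 4L)

  iso <- metab_network(c("z", "a", "m"))
  expect_equal(rank_by_degree(iso)$pathway_id, c("a", "m", "z"))

  withr::with_seed(13, {
    u <- random_universe()
    net <- build_network(u)
    rk <- rank_by_degree(net)
    d <- network_degrees(net)
    expect_equal(rk$degree, unname(d[rk$pathway_id]))
    expect_equal(rk$degree, sort(rk$degree, decreasing = TRUE))
  })
})

test_that("hub enrichment wires ranking into the mHG test", {
  net <- metab_network(c("hub", paste0("leaf", 1:4)),
                       data.frame(from = "hub", to = paste0("leaf", 1:4)),
                       enriched = "hub")
  r <- network_hub_enrichment(net)
  expect_s3_class(r, "mhg_result")
  expect_equal(r$cutoff, 1L)
  avg <- network_hub_enrichment(net, tie_policy = "average",
                                n_tie_perm = 10, seed = 2)
  expect_true(is.finite(avg$mean_p_value))
})

test_that("degree comparison reproduces the hand-computed U statistic", {
  path <- metab_network(paste0("p", 1:7),
                        data.frame(from = paste0("p", 1:6),
                                   to = paste0("p", 2:7)),
                        enriched = c("p2", "p3", "p4"))
  r <- compare_degree_distributions(path)
  expect_equal(r$mean_enriched, 2)
  expect_equal(r$mean_other, (1 + 2 + 2 + 1) / 4)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_error(compare_degree_distributions(
    metab_network("p1", enriched = "p1")), "non-empty")
})

test_that("U convention counts pairwise wins of the enriched group", {
  # degrees {4,5,6} vs {1,2,3} -> U = 9
  expect_equal(unname(suppressWarnings(
    stats::wilcox.test(c(4, 5, 6), c(1, 2, 3), exact = FALSE)$statistic)), 9)
  # mirrored through a synthetic network where enriched nodes are hubs
  cfg <- small_synth_config(seed = 4)
  uni <- generate_universe(cfg)
  net <- build_network(uni$universe,
                       enriched = rank_by_degree(
                         build_network(uni$universe))$pathway_id[1:3])
  r <- compare_degree_distributions(net)
  expect_gt(r$mean_enriched, r$mean_other)
})

test_that("distance shells are BFS-minimal and partition reachable nodes", {
  path <- metab_network(c("A", "B", "C"),
                        data.frame(from = c("A", "B"), to = c("B", "C")))
  sh <- distance_shells(path, "A")
  expect_equal(sh$shells, list(`1` = "B", `2` = "C"))

  # merged-target semantics: a node adjacent to both targets sits in
  # shell 1 exactly once
  y <- metab_network(c("T1", "T2", "X"),
                     data.frame(from = c("T1", "T2"), to = c("X", "X")))
  shy <- distance_shells(y, c("T1", "T2"))
  expect_equal(shy$shells, list(`1` = "X"))
  # strict per-target mode assigns the larger distance
  line <- metab_network(c("T1", "X", "T2", "Y"),
                        data.frame(from = c("T1", "X", "T2"),
                                   to = c("X", "T2", "Y")))
  expect_equal(distance_shells(line, c("T1", "T2"))$distances[["X"]], 1)
  expect_equal(distance_shells(line, c("T1", "T2"),
                               mode = "max")$distances[["X"]], 1)
  expect_equal(distance_shells(line, c("T1", "T2"),
                               mode = "max")$distances[["Y"]], 3)

  withr::with_seed(55, {
    for (i in 1:5) {
      u <- random_universe(n_pathways = 15, n_compounds = 8)
      net <- build_network(u)
      targets <- sample(net$nodes, 2)
      sh <- distance_shells(net, targets)
      fw <- floyd_warshall(net)
      for (v in setdiff(net$nodes, targets)) {
        want <- min(fw[targets, v])
        got <- sh$distances[[v]]
        if (is.infinite(want)) expect_true(v %in% sh$unreachable)
        else expect_equal(got, want)
      }
      # shells partition reachable non-target nodes
      assigned <- unlist(sh$shells, use.names = FALSE)
      expect_equal(sort(c(assigned, sh$unreachable)),
                   sort(setdiff(net$nodes, targets)))
      expect_false(anyDuplicated(assigned) > 0)
    }
  })
})

test_that("shell enrichment applies the hypergeometric per shell", {
  sh <- structure(list(shells = list(`1` = c("a", "b"), `2` = c("c", "d", "e")),
                       distances = c(a = 1, b = 1, c = 2, d = 2, e = 2),
                       unreachable = character()),
                  class = "distance_shells")
  se <- shell_enrichment(sh, enriched = c("a", "b"))
  expect_equal(se$p_value[se$distance == 1],
               hypergeom_upper_tail(2, 2, 2, 5))
  # degenerate single shell: k = K, n = N -> p = 1
  one <- structure(list(shells = list(`1` = c("a", "b", "c"))),
                   class = "distance_shells")
  expect_equal(shell_enrichment(one, c("a", "b"))$p_value, 1.0)
  # uniform scatter behaves like a valid p-value under permutation
  withr::with_seed(77, {
    u <- random_universe(n_pathways = 25, n_compounds = 10)
    net <- build_network(u)
    sh2 <- distance_shells(net, net$nodes[1])
    assigned <- unlist(sh2$shells, use.names = FALSE)
    if (length(assigned) >= 10) {
      ps <- replicate(200, {
        enr <- sample(assigned, 4)
        min(shell_enrichment(sh2, enr)$p_value)
      })
      # minimal p over shells under the null is rarely tiny
      expect_gt(mean(ps > 0.01), 0.5)
    }
  })
})

test_that("distance comparison reproduces a hand-computed Welch t", {
  sh <- structure(list(distances = c(a = 1, b = 1, c = 2, d = 2,
                                     e = 3, f = 3, g = 4, h = 4)),
                  class = "distance_shells")
  r <- compare_distance_distributions(sh, enriched = c("a", "b", "c", "d"))
  m1 <- 1.5; m2 <- 3.5; s2 <- var(c(1, 1, 2, 2))
  t_hand <- (m1 - m2) / sqrt(s2 / 4 + s2 / 4)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$mean_enriched, 1.5)
  # identical multisets: t = 0, p = 1
  sh2 <- structure(list(distances = c(a = 1, b = 2, c = 1, d = 2)),
                   class = "distance_shells")
  r2 <- compare_distance_distributions(sh2, enriched = c("a", "b"))
  expect_equal(r2$t, 0)
  expect_equal(r2$p_value, 1)
  expect_error(compare_distance_distributions(sh2, enriched = "a"), ">= 2")
  # pooled variant is exposed
  rp <- compare_distance_distributions(sh, c("a", "b", "c", "d"),
                                       var = "pooled", verbose = TRUE)
  expect_true(is.finite(rp$welch$p_value))
})

test_that("network export round-trips in both formats", {
  net <- metab_network(c("A", "B", "C", "D"),
                       data.frame(from = c("A", "B"), to = c("B", "C")),
                       enriched = c("A", "C"))
  for (fmt in c("edgelist", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, f, fmt)
    back <- import_network(f, fmt)
    expect_setequal(back$nodes, net$nodes)
    expect_equal(back$edges, net$edges)
    expect_setequal(back$enriched, net$enriched)
  }
  # graphml structure: 4 node elements, 2 edge elements
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='node']"), 4L)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='edge']"), 2L)
  # empty network round-trips too
  empty <- metab_network(character())
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, f2, "edgelist")
  expect_equal(length(import_network(f2)$nodes), 0L)
  expect_error(export_network(net, f, "dot"))
})

test_that("statistics are invariant under node relabeling", {
  withr::with_seed(61, {
    u <- random_universe(n_pathways = 18, n_compounds = 9)
    net <- build_network(u, enriched = sample(u$pathway_id, 5))
    perm <- stats::setNames(sprintf("q%02d", sample(18)), net$nodes)
    net2 <- metab_network(unname(perm[net$nodes]),
                          data.frame(from = unname(perm[net$edges$from]),
                                     to = unname(perm[net$edges$to])),
                          enriched = unname(perm[net$enriched]))
    expect_equal(sort(unname(network_degrees(net))),
                 sort(unname(network_degrees(net2))))
    r1 <- compare_degree_distributions(net)
    r2 <- compare_degree_distributions(net2)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$mean_enriched, r2$mean_enriched)
  })
})
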