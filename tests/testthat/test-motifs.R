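test_that("reaction graphs load from TSV with enrichment flags resolved", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# pathway_id: ko99999",
               "reaction_id\tsubstrate\tproduct\tkos",
               "r1\tc1\tc2\tK1;K9",
               "r2\tc2\tc3\tK2",
               "r3\tc3\tc4\tK3",
               "r4\tc4\tc5\tK4"), tmp)
  g <- read_reaction_graph(tmp, enriched_kos = c("K9", "K4"))
  expect_equal(g$pathway_id, "ko99999")
  expect_length(g$compounds, 5L)
  expect_equal(nrow(g$reactions), 4L)
  expect_equal(g$reactions$enriched, c(TRUE, FALSE, FALSE, TRUE))

  # round-trip through write/read preserves structure
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_graph(g, f)
  back <- read_reaction_graph(f, enriched_kos = c("K9", "K4"))
  expect_equal(back$reactions$reaction_id, g$reactions$reaction_id)
  expect_equal(back$reactions$kos, g$reactions$kos, ignore_attr = TRUE)
  expect_equal(back$reactions$enriched, g$reactions$enriched)

  # undeclared compound is a hard error
  expect_error(reaction_graph(data.frame(reaction_id = "r1", substrate = "c1",
                                         product = "c2", kos = "K1"),
                              compounds = "c1"), "undeclared")
})

test_that("KGML maps parse into reaction graphs", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:ko00030" org="ko" number="00030">',
    '  <entry id="1" name="ko:K01623" type="ortholog" reaction="rn:R01068"/>',
    '  <entry id="2" name="ko:K01808 ko:K99999" type="ortholog" reaction="rn:R01056"/>',
    '  <reaction id="10" name="rn:R01068" type="irreversible">',
    '    <substrate id="20" name="cpd:C00354"/>',
    '    <product id="21" name="cpd:C00111"/>',
    '  </reaction>',
    '  <reaction id="11" name="rn:R01056" type="reversible">',
    '    <substrate id="22" name="cpd:C00117"/>',
    '    <product id="23" name="cpd:C00199"/>',
    '  </reaction>',
    '</pathway>'), tmp)
  g <- read_kgml(tmp, enriched_kos = "K01808")
  expect_equal(nrow(g$reactions), 2L)
  expect_setequal(g$compounds, c("C00354", "C00111", "C00117", "C00199"))
  expect_equal(g$reactions$enriched[g$reactions$reaction_id == "R01056"], TRUE)
  expect_equal(g$reactions$enriched[g$reactions$reaction_id == "R01068"], FALSE)
})

test_that("the linear worked chain yields exactly one motif scored 0.140625", {
  g <- linear_chain_graph()
  motifs <- find_motifs(g)
  expect_length(motifs, 1L)
  m <- motifs[[1]]
  expect_equal(m$reactions, paste0("r", 1:4))
  expect_equal(m$n_enriched, 3L)
  expect_equal(m$n_nonenriched, 1L)
  pv <- motif_pvalue(m, g)
  expect_equal(as.numeric(pv), 0.140625, tolerance = 1e-12)
  terms <- attr(pv, "terms")
  expect_equal(terms$term, c(0.75, 0.25, 0.75))
  expect_equal(terms$n, c(1L, 1L, 1L))
})

test_that("motif mining edge cases", {
  g <- linear_chain_graph()
  g$reactions$enriched <- rep(FALSE, 4)
  expect_length(find_motifs(g), 0L)

  # all enriched: one maximal motif covering the chain, p-value 1
  g2 <- linear_chain_graph()
  g2$reactions$enriched <- rep(TRUE, 4)
  m2 <- find_motifs(g2)
  expect_length(m2, 1L)
  expect_equal(as.numeric(motif_pvalue(m2[[1]], g2)), 1.0)

  # symmetric binomial point mass at a branch: C(2,1) 0.5 * 0.5 = 0.5
  rx <- data.frame(reaction_id = paste0("r", 1:4),
                   substrate = c("a", "b", "c", "b"),
                   product = c("b", "c", "d", "e"),
                   kos = c("K1", "K2", "K3", "K4"))
  gb <- reaction_graph(rx, enriched_kos = c("K1", "K2"))
  # p = 2/4 = 0.5; transition into b from r1: incident {r1,r2,r4} minus
  # r1 -> n = 2, y = 1
  motif <- list(reactions = c("r1", "r2"), compounds = c("a", "b", "c"))
  class(motif) <- "motif"
  pv <- motif_pvalue(motif, gb)
  expect_equal(attr(pv, "terms")$term[1], 0.5)

  # include_first mode adds a term for the first reaction
  m <- find_motifs(g2)[[1]]
  pv_first <- motif_pvalue(m, g2, include_first = TRUE)
  expect_equal(nrow(attr(pv_first, "terms")), 4L)
  # tail mode: upper tail of y successes is >= the point mass at the max
  pv_tail <- motif_pvalue(m, g2, mode = "tail")
  expect_gte(as.numeric(pv_tail), as.numeric(motif_pvalue(m, g2)))
})

test_that("mined motifs always satisfy their own invariants", {
  withr::with_seed(71, {
    for (i in 1:40) {
      g <- random_reaction_graph(sample(5:12, 1))
      for (m in find_motifs(g)) {
        expect_gte(length(m$reactions), 4L)
        expect_gte(m$n_enriched, 3L)
        expect_lte(m$n_nonenriched, 1L)
        expect_false(anyDuplicated(m$reactions) > 0)
        # consecutive: product of step i is substrate of step i+1
        expect_equal(length(m$compounds), length(m$reactions) + 1L)
        pv <- as.numeric(motif_pvalue(m, g))
        expect_true(pv > 0 && pv <= 1)
      }
    }
  })
})

test_that("motif mining equals exhaustive enumeration on random graphs", {
  canon <- function(ms) sort(vapply(ms, function(m)
    paste(m$reactions, collapse = ";"), character(1)))
  withr::with_seed(72, {
    for (i in 1:60) {
      g <- random_reaction_graph(sample(6:11, 1))
      expect_equal(canon(find_motifs(g)), canon(enum_motifs(g)),
                   label = paste("graph", i))
    }
    # undirected traversal mode against the oracle too
    for (i in 1:15) {
      g <- random_reaction_graph(sample(5:9, 1))
      expect_equal(canon(find_motifs(g, undirected = TRUE)),
                   canon(enum_motifs(g, undirected = TRUE)),
                   label = paste("undirected graph", i))
    }
  })
})

test_that("sub-chain mode reports every qualifying chain", {
  rx <- data.frame(reaction_id = paste0("r", 1:5),
                   substrate = paste0("c", 1:5), product = paste0("c", 2:6),
                   kos = paste0("K", 1:5))
  g <- reaction_graph(rx, enriched_kos = paste0("K", 1:5))
  maximal <- find_motifs(g)
  all_chains <- find_motifs(g, maximal = FALSE)
  expect_length(maximal, 1L)
  expect_equal(length(all_chains), 3L)   # lengths 4, 4, 5
})

test_that("extra all-enriched transition contracts the p-value by p", {
  rx <- data.frame(reaction_id = paste0("r", 1:5),
                   substrate = paste0("c", 1:5), product = paste0("c", 2:6),
                   kos = paste0("K", 1:5))
  g <- reaction_graph(rx, enriched_kos = c("K1", "K2", "K4", "K5"))
  p <- mean(g$reactions$enriched)
  m4 <- list(reactions = paste0("r", 1:4), compounds = paste0("c", 1:5))
  m5 <- list(reactions = paste0("r", 1:5), compounds = paste0("c", 1:6))
  class(m4) <- class(m5) <- "motif"
  expect_equal(as.numeric(motif_pvalue(m5, g)),
               as.numeric(motif_pvalue(m4, g)) * p, tolerance = 1e-12)
})

test_that("motif detection rate grows with the enriched fraction", {
  count_at <- function(p_enr) {
    n <- 0
    for (s in 1:12) {
      withr::with_seed(1000 + s, g <- random_reaction_graph(10, p_enriched = p_enr))
      n <- n + length(find_motifs(g))
    }
    n
  }
  expect_lte(count_at(0.2), count_at(0.9))
})

test_that("motif report flags significance without dropping rows", {
  g <- linear_chain_graph()
  rep <- motif_report(g, significance = 0.2)
  expect_equal(nrow(rep), 1L)
  expect_true(rep$significant)
  rep2 <- motif_report(g, significance = 0.05)
  expect_false(rep2$significant)
  expect_equal(rep2$p_value, 0.140625)
})
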