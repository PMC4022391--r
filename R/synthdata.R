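#' Configuration for the synthetic-data generator
#'
#' The generator emulates the inputs of a marine comparative-metagenomic
#' study: a large background metagenome annotated against an
#' ortholog-group database, a much smaller viral subset (or a paired
#' virome), a pathway universe at the scale of the KEGG metabolic-pathway
#' collection, and small per-pathway reaction graphs.  Background KO
#' abundances follow a log-uniform law (heavy-tailed, as in real
#' metagenomes); planted KOs get a fold-enrichment in the viral set and
#' are drawn with background weights in the upper abundance decade, the
#' regime where a fold-20 effect at these sample sizes is detectable.
#'
#' @param seed integer seed; fixing it makes every emitted artifact
#'   byte-identical across runs.
#' @param n_pathways number of pathways in the universe (default 148, the
#'   size of the KEGG metabolic-pathway collection).
#' @param ko_pool number of distinct KOs the background can draw from.
#' @param kos_per_pathway integer range of member KOs per pathway.
#' @param compound_pool number of distinct shared compounds.
#' @param substrates_per_pathway,products_per_pathway integer ranges of
#'   substrate / product compounds per pathway (drawn from the shared
#'   pool; sharing density controls network connectivity).
#' @param reactions_per_pathway integer range of reactions per pathway
#'   reaction graph.
#' @param n_background_reads,n_subset_reads read counts for the
#'   background and viral sets.
#' @param n_planted number of planted (fold-enriched) KOs.
#' @param planted_fold fold-enrichment of planted KOs in the viral set.
#' @param abundance_decades span (in decades) of the log-uniform
#'   background abundance law.
#' @param evalue_log10_range log10 range of simulated e-values; with the
#'   default (-20, -3) a fixed fraction of annotations fails the `< 1e-5`
#'   filter.
#' @param identity_range percent-identity range (uniform).
#' @param multi_ko_fraction fraction of reads carrying a second, distinct
#'   KO annotation.
#' @param cluster_fraction fraction of viral-set reads wrapped into
#'   MG-RAST-style `aa90_` clusters.
#' @param cluster_size integer range of cluster sizes.
#' @param design `"superset"` (viral reads are a literal subset of the
#'   background) or `"paired"` (independent virome / microbiome samples).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_pathways = 148L, ko_pool = 800L,
                         kos_per_pathway = c(5L, 30L), compound_pool = 300L,
                         substrates_per_pathway = c(2L, 6L),
                         products_per_pathway = c(2L, 6L),
                         reactions_per_pathway = c(6L, 14L),
                         n_background_reads = 200000L,
                         n_subset_reads = 2000L,
                         n_planted = 8L, planted_fold = 20,
                         abundance_decades = 3,
                         evalue_log10_range = c(-20, -3),
                         identity_range = c(50, 100),
                         multi_ko_fraction = 0.02,
                         cluster_fraction = 0.1,
                         cluster_size = c(2L, 4L),
                         design = c("superset", "paired")) {
  design <- match.arg(design)
  cfg <- list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
              ko_pool = as.integer(ko_pool),
              kos_per_pathway = as.integer(kos_per_pathway),
              compound_pool = as.integer(compound_pool),
              substrates_per_pathway = as.integer(substrates_per_pathway),
              products_per_pathway = as.integer(products_per_pathway),
              reactions_per_pathway = as.integer(reactions_per_pathway),
              n_background_reads = as.integer(n_background_reads),
              n_subset_reads = as.integer(n_subset_reads),
              n_planted = as.integer(n_planted),
              planted_fold = as.numeric(planted_fold),
              abundance_decades = as.numeric(abundance_decades),
              evalue_log10_range = as.numeric(evalue_log10_range),
              identity_range = as.numeric(identity_range),
              multi_ko_fraction = as.numeric(multi_ko_fraction),
              cluster_fraction = as.numeric(cluster_fraction),
              cluster_size = as.integer(cluster_size),
              design = design)
  stopifnot(cfg$n_pathways >= 1, cfg$ko_pool >= max(cfg$kos_per_pathway),
            cfg$planted_fold >= 1, cfg$n_subset_reads >= 0,
            cfg$n_background_reads >= cfg$n_subset_reads || design == "paired",
            cfg$multi_ko_fraction >= 0, cfg$cluster_fraction >= 0)
  structure(cfg, class = "synth_config")
}

.rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a synthetic pathway universe with reaction graphs
#'
#' Draws pathway memberships from a shared KO pool and substrate/product
#' compound sets from a shared compound pool (shared compounds are what
#' create edges in the downstream metabolism network), builds one
#' reaction graph per pathway (a backbone chain of consecutive reactions
#' plus a few branch reactions, each labelled with member KOs), assigns
#' log-uniform background abundances to every KO, and plants
#' fold-enriched KOs: two focus pathways contribute three planted member
#' KOs each (so some pathways carry multiple planted KOs, mirroring the
#' clustering of auxiliary genes in nucleotide-metabolism pathways) and
#' the remainder are drawn at random from other pathway members.  Planted
#' KOs get abundance weights in the top decade of the law.
#'
#' @param cfg a [synth_config()].
#' @return list with `universe` (a `pathway_universe`),
#'   `reaction_graphs` (named list of `reaction_graph`s) and `truth`
#'   (planted KO table, per-KO background probabilities, focus pathways).
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    kos <- sprintf("K%05d", seq_len(cfg$ko_pool))
    compounds <- sprintf("C%05d", seq_len(cfg$compound_pool))
    pids <- sprintf("syn%05d", seq_len(cfg$n_pathways))
    members <- lapply(.rint(cfg$n_pathways, cfg$kos_per_pathway),
                      function(m) sample(kos, m))
    subs <- lapply(.rint(cfg$n_pathways, cfg$substrates_per_pathway),
                   function(m) sample(compounds, m))
    prods <- lapply(.rint(cfg$n_pathways, cfg$products_per_pathway),
                    function(m) sample(compounds, m))
    universe <- pathway_universe(pids, paste("Synthetic pathway", pids),
                                 members, subs, prods)
    # abundance law: weights 10^U(0, D); planted KOs re-drawn in the top
    # decade so the planted effect is detectable at the default depths
    w <- 10^stats::runif(cfg$ko_pool, 0, cfg$abundance_decades)
    names(w) <- kos
    in_universe <- unique(unlist(members, use.names = FALSE))
    n_focus <- min(2L, cfg$n_pathways)
    focus <- sample(pids, n_focus)
    planted <- character()
    for (pid in focus)
      planted <- union(planted,
                       sample(universe$members[[pid]],
                              min(3L, length(universe$members[[pid]]))))
    extra <- setdiff(in_universe, planted)
    if (length(planted) < cfg$n_planted && length(extra))
      planted <- c(planted, sample(extra, min(cfg$n_planted - length(planted),
                                              length(extra))))
    planted <- utils::head(planted, cfg$n_planted)
    w[planted] <- 10^stats::runif(length(planted),
                                  cfg$abundance_decades - 1,
                                  cfg$abundance_decades)
    graphs <- stats::setNames(lapply(pids, function(pid)
      .synth_reaction_graph(pid, universe$members[[pid]], cfg)), pids)
    truth <- list(planted = data.frame(ko_id = sort(planted),
                                       fold = rep(cfg$planted_fold,
                                                  length(planted)),
                                       stringsAsFactors = FALSE),
                  background_probs = w / sum(w),
                  focus_pathways = focus)
    list(universe = universe, reaction_graphs = graphs, truth = truth)
  })
}

# backbone chain c1 -> c2 -> ... plus ~20% branch reactions between
# random backbone compounds; KO labels drawn from the pathway's members
.synth_reaction_graph <- function(pid, member_kos, cfg) {
  n_rx <- .rint(1, cfg$reactions_per_pathway)
  cmp <- sprintf("%s_c%02d", pid, seq_len(n_rx + 1))
  sub <- cmp[seq_len(n_rx)]
  prod <- cmp[seq_len(n_rx) + 1]
  n_branch <- max(0L, round(0.2 * n_rx))
  if (n_branch > 0 && n_rx >= 3) {
    b_from <- sample(cmp, n_branch, replace = TRUE)
    b_to <- sample(cmp, n_branch, replace = TRUE)
    keep <- b_from != b_to
    sub <- c(sub, b_from[keep])
    prod <- c(prod, b_to[keep])
  }
  kos <- lapply(seq_along(sub), function(i)
    sample(member_kos, min(length(member_kos), sample(1:2, 1))))
  reaction_graph(data.frame(reaction_id = sprintf("%s_r%02d", pid,
                                                  seq_along(sub)),
                            substrate = sub, product = prod,
                            stringsAsFactors = FALSE) |>
                   transform(kos = I(kos)),
                 enriched_kos = character(), pathway_id = pid)
}

#' Generate a background / viral annotation-set pair
#'
#' Background reads draw their KO from the background abundance law; the
#' viral set is either a weighted sample *of the background reads
#' themselves* (superset design: planted KOs' reads are
#' `planted_fold`-times as likely to be picked, and every viral record
#' exists verbatim in the background) or an independent draw from the
#' fold-reweighted law with fresh read ids (paired design).  E-values are
#' log-uniform and identities uniform, so a known fraction of records
#' fails the standard quality filters; a configurable fraction of viral
#' reads is wrapped into `aa90_`-style clusters (members of a cluster
#' share their quality values, as sequence-identical reads would).
#'
#' @param bundle output of [generate_universe()].
#' @param cfg the same [synth_config()].
#' @return list with `background`, `subset` (cluster-compressed form),
#'   `subset_expanded` (ground-truth read-level form), `mapping` (a
#'   `cluster_mapping`), and `truth` (planted table plus the generator's
#'   ledger of KO counts for both sets, counted before quality
#'   filtering).
#' @export
generate_metagenome_pair <- function(bundle, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  probs <- bundle$truth$background_probs
  kos <- names(probs)
  planted <- bundle$truth$planted
  fold <- stats::setNames(rep(1, length(kos)), kos)
  fold[planted$ko_id] <- planted$fold
  withr::with_seed(cfg$seed + 1000L, {
    n_bg <- cfg$n_background_reads
    bg_reads <- sprintf("S%d_R%06d", cfg$seed, seq_len(n_bg))
    bg_ko <- sample(kos, n_bg, replace = TRUE, prob = probs)
    # a small fraction of reads carries a second, distinct KO
    n_multi <- round(cfg$multi_ko_fraction * n_bg)
    multi_idx <- if (n_multi) sample.int(n_bg, n_multi) else integer()
    second_ko <- if (n_multi) sample(kos, n_multi, replace = TRUE, prob = probs)
                 else character()
    keep2 <- second_ko != bg_ko[multi_idx]
    bg <- data.frame(read_id = c(bg_reads, bg_reads[multi_idx][keep2]),
                     ko_id = c(bg_ko, second_ko[keep2]),
                     stringsAsFactors = FALSE)
    bg$e_value <- 10^stats::runif(nrow(bg), cfg$evalue_log10_range[1],
                                  cfg$evalue_log10_range[2])
    bg$pct_identity <- stats::runif(nrow(bg), cfg$identity_range[1],
                                    cfg$identity_range[2])
    if (cfg$design == "superset") {
      # per-read pick weight: the largest fold among its annotations;
      # weighted sampling without replacement via exponential race keys
      # (with equal weights this reduces to uniform sampling, so null KOs
      # follow the hypergeometric exactly)
      read_w <- unname(fold[bg_ko])
      mi <- multi_idx[keep2]
      read_w[mi] <- pmax(read_w[mi], unname(fold[second_ko[keep2]]))
      keys <- stats::rexp(n_bg) / read_w
      pick <- bg_reads[order(keys)[seq_len(cfg$n_subset_reads)]]
      sub <- bg[bg$read_id %in% pick, , drop = FALSE]
    } else {
      p_vir <- probs * fold
      p_vir <- p_vir / sum(p_vir)
      vir_reads <- sprintf("V%d_R%06d", cfg$seed, seq_len(cfg$n_subset_reads))
      vir_ko <- sample(kos, cfg$n_subset_reads, replace = TRUE, prob = p_vir)
      sub <- data.frame(read_id = vir_reads, ko_id = vir_ko,
                        stringsAsFactors = FALSE)
      sub$e_value <- 10^stats::runif(nrow(sub), cfg$evalue_log10_range[1],
                                     cfg$evalue_log10_range[2])
      sub$pct_identity <- stats::runif(nrow(sub), cfg$identity_range[1],
                                       cfg$identity_range[2])
    }
    cl <- .wrap_clusters(sub, cfg)
    sub_expanded <- cl$expanded
    if (cfg$design == "superset") {
      # keep the background verbatim-consistent with the harmonised
      # cluster-member quality values
      key_bg <- paste(bg$read_id, bg$ko_id)
      key_ex <- paste(sub_expanded$read_id, sub_expanded$ko_id)
      hit <- match(key_bg, key_ex)
      bg$e_value[!is.na(hit)] <- sub_expanded$e_value[hit[!is.na(hit)]]
      bg$pct_identity[!is.na(hit)] <- sub_expanded$pct_identity[hit[!is.na(hit)]]
    }
    ledger_bg <- table(bg$ko_id)
    ledger_sub <- table(sub_expanded$ko_id)
    truth <- list(planted = planted,
                  background_counts = stats::setNames(as.integer(ledger_bg),
                                                      names(ledger_bg)),
                  subset_counts = stats::setNames(as.integer(ledger_sub),
                                                  names(ledger_sub)),
                  design = cfg$design)
    list(background = annotation_set(bg$read_id, bg$ko_id, bg$e_value,
                                     bg$pct_identity, "background"),
         subset = annotation_set(cl$clustered$read_id, cl$clustered$ko_id,
                                 cl$clustered$e_value, cl$clustered$pct_identity,
                                 "viral"),
         subset_expanded = annotation_set(sub_expanded$read_id,
                                          sub_expanded$ko_id,
                                          sub_expanded$e_value,
                                          sub_expanded$pct_identity, "viral"),
         mapping = cl$mapping, truth = truth)
  })
}

# wrap a fraction of same-KO viral reads into aa90_ clusters; members of a
# cluster are harmonised to one e-value / identity (they stand for
# near-identical sequences), so cluster expansion reproduces the
# read-level truth exactly
.wrap_clusters <- function(sub, cfg) {
  expanded <- sub
  clustered <- sub
  mapping <- list()
  n_target <- round(cfg$cluster_fraction * length(unique(sub$read_id)))
  if (n_target >= min(cfg$cluster_size)) {
    by_ko <- split(seq_len(nrow(sub)), sub$ko_id)
    by_ko <- by_ko[lengths(by_ko) >= min(cfg$cluster_size)]
    taken <- 0L
    cl_id <- 0L
    drop_rows <- integer()
    add_rows <- list()
    used_reads <- character()
    for (rows in by_ko) {
      if (taken >= n_target) break
      rows <- rows[!(sub$read_id[rows] %in% used_reads)]
      if (length(rows) < min(cfg$cluster_size)) next
      size <- min(.rint(1, cfg$cluster_size), length(rows))
      pick <- rows[seq_len(size)]
      cl_id <- cl_id + 1L
      cname <- sprintf("aa90_%d", cl_id)
      e <- min(sub$e_value[pick])
      id <- max(sub$pct_identity[pick])
      mapping[[cname]] <- sub$read_id[pick]
      used_reads <- c(used_reads, sub$read_id[pick])
      expanded$e_value[pick] <- e
      expanded$pct_identity[pick] <- id
      drop_rows <- c(drop_rows, pick)
      add_rows[[cl_id]] <- data.frame(read_id = cname,
                                      ko_id = sub$ko_id[pick[1]],
                                      e_value = e, pct_identity = id,
                                      stringsAsFactors = FALSE)
      taken <- taken + size
    }
    if (length(drop_rows))
      clustered <- rbind(sub[-drop_rows, , drop = FALSE],
                         do.call(rbind, add_rows))
  }
  list(clustered = clustered, expanded = expanded,
       mapping = cluster_mapping(mapping))
}

#' Write a full synthetic dataset to disk
#'
#' Emits, under `dir`: `background.tsv` and `subset.tsv` (annotation
#' tables in the canonical dialect), `cluster_mapping.tsv`,
#' `pathway_universe.tsv`, one `reactions/<pathway>.tsv` per pathway,
#' `ground_truth.tsv` (planted KOs and folds) and `manifest.json`
#' recording the full configuration -- the exact file dialects the
#' package's readers consume.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return the generated objects (as from [generate_universe()] and
#'   [generate_metagenome_pair()]), invisibly.
#' @export
write_synth_bundle <- function(cfg, dir) {
  dir.create(file.path(dir, "reactions"), recursive = TRUE, showWarnings = FALSE)
  uni <- generate_universe(cfg)
  pair <- generate_metagenome_pair(uni, cfg)
  write_annotation_table(pair$background, file.path(dir, "background.tsv"))
  write_annotation_table(pair$subset, file.path(dir, "subset.tsv"))
  write_cluster_mapping(pair$mapping, file.path(dir, "cluster_mapping.tsv"))
  write_pathway_definitions(uni$universe, file.path(dir, "pathway_universe.tsv"))
  for (pid in names(uni$reaction_graphs))
    write_reaction_graph(uni$reaction_graphs[[pid]],
                         file.path(dir, "reactions", paste0(pid, ".tsv")))
  utils::write.table(uni$truth$planted, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(universe = uni, pair = pair))
}
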