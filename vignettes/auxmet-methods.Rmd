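---
title: "Methods: viral enrichment of metabolic ortholog groups, pathway scoring, network placement and motif mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral enrichment of metabolic ortholog groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxmet)
```

# The analysis model

`auxmet` implements a comparative-metagenomic pipeline for auxiliary
metabolic genes: host-derived enzymes carried by marine viruses. The
pipeline starts from *annotations*, not sequences — each input record says
that a sequencing read was assigned to a KEGG Ortholog (KO) with a given
e-value and percent identity. Everything downstream treats the annotated
read as the unit of evidence.

Two sampling designs are supported, matching the two kinds of marine
datasets this analysis is used on:

* **Superset design** — the viral set is a literal subset of the
  background (viral-classified scaffolds inside a larger survey, converted
  to their reads). Conditioning on the background composition, the count
  of a KO among the viral annotations is exactly hypergeometric, and
  over-representation is `hypergeom_upper_tail(k, K, n, N)`.
* **Paired design** — virome and microbiome are two independent samples
  from the same site (size-fraction filtering). No subset structure
  exists, so the one-sided Fisher exact test applies;
  `fisher_exact_greater()` evaluates it through the conditional-margins
  identity, i.e. as a hypergeometric tail with both margins fixed.

Two deliberate statistical choices deserve mention. First, the classical
presentation of the hypergeometric "probability test" is a *point mass*
P(X = k); a point mass is not a usable enrichment p-value (it punishes
large, expected counts as much as surprising ones), so the pipeline uses
the upper tail P(X ≥ k) and retains `hypergeom_point_mass()` for fidelity
checks. Second, the enrichment call applies a *raw* threshold
α = 10⁻⁴ with no multiple-testing correction — the convention used in
the published VirMic and Line-Islands analyses, which keeps called lists
comparable with theirs;
Benjamini–Hochberg adjustment is available behind
`adjust_pvalues(method = "BH")` for users who prefer FDR control.

## Annotation handling

Quality filters are strict inequalities — e-value < 10⁻⁵, and, when the
identity filter is enabled for short-read data, identity > 75 % — because
that is how the thresholds are conventionally stated. Duplicate
(read, KO) pairs collapse to the smallest e-value (first occurrence on
ties) so the same read never counts twice for one KO. A read annotated to
two *different* KOs contributes to both by default: the counting unit is
the (read, KO) pair. This is the least destructive reading of
"counting KO appearances in reads"; a `best_hit` mode (one count per
read, to its lowest-e-value KO) is exposed in `count_kos()` for users who
want best-hit semantics.

MG-RAST-style exports sometimes compress near-identical reads into
`aa90_` clusters; `expand_clusters()` restores read-level records by
copying the cluster record's annotation onto every member. Unmapped
cluster ids are kept (with a warning pattern available in strict mode)
rather than dropped, since dropping silently deflates counts.

## The pathway enrichment score

For a pathway with *T* member KOs of which *N* are enriched with p-values
*P₁…P_N*,

$$ES = N \cdot \frac{\sum_{n=1}^{N} -\log_{10} P_n}{T}.$$

The score is additive in the per-KO weights w = −log₁₀ P, scaled by the
enriched fraction N/T. Additivity has a useful consequence: when a KO
appears in several pathways (modularity is pervasive among auxiliary
genes), it must contribute the *same* weight to each, so a published
score table over-determines the weights. `solve_ko_weights()` propagates
single-unknown row constraints (Σw = ES·T/N per row);
`check_score_consistency()` generalises this to minimum-norm least
squares over designated source rows and re-predicts a held-out row,
refusing (with an error) when the held-out row's KO-indicator is outside
the row space of the sources — in that case the prediction would be
arbitrary. This is the machinery behind `scripts/acceptance.R`, which
reproduces eight held-out rows of the shipped published table to printed
precision. One published row (pyrimidine metabolism) states ten enriched
KOs but lists nine identifiers; being internally inconsistent, it is
never used as a source row.

A configurable p-value floor (default 10⁻³⁰⁰) keeps scores finite; a
p-value of exactly zero is an error with guidance rather than a silent
infinity.

## The global metabolism network

Pathways are nodes; an undirected, unweighted edge joins A and B whenever
some product compound of one is a substrate compound of the other — the
network of possible metabolite hand-offs. An exclusion list for currency
metabolites (water, ATP, …) is supported but *empty by default*: with no
compound curation shipped, silently dropping compounds would be a larger
distortion than the spurious edges they create.

Three analyses run on this network:

* **Hub concentration (mHG).** Pathways are ranked by degree and the
  enriched indicator vector is tested with the minimal hypergeometric
  statistic: the minimum over prefix lengths ℓ of the hypergeometric
  upper tail of the ones seen in the top ℓ. Because the cutoff is
  optimised, the statistic is not a p-value; `mhg_test()` computes the
  exact p-value by lattice-path counting (dynamic programming over
  (prefix, ones) states, excluding the rejection region), with a
  Monte-Carlo permutation fallback for validation. Degree ties are broken
  lexicographically for determinism, and because ties materially affect
  ranked-list statistics, `network_hub_enrichment(tie_policy = "average")`
  averages over random tie orders as a sensitivity check. Note that the
  statistic is *not* invariant to appending non-enriched pathways: they
  enlarge the population and dilute every prefix tail, so the statistic
  can only decrease — the test suite checks exactly this monotonicity.
* **Degree distributions.** Two-sided Mann–Whitney with tie correction
  (`wilcox.test`, normal approximation); the reported U counts pairwise
  wins of the enriched group.
* **Path-length shells.** Breadth-first distance from a merged target
  set (default reading: distance to the *nearest* of the targets, which
  matches treating the two nucleotide-metabolism pathways as one hub); a
  strict `mode = "max"` assigns each pathway its largest per-target
  distance instead, for the "connected to both" reading. Targets sit at
  distance 0 and are excluded from shells; unreachable pathways are
  reported but excluded from shell statistics, since an infinite distance
  has no place in either the shell hypergeometric or the t-test. Per
  shell, over-representation is the hypergeometric tail with the
  shell-assigned pathways as population. Distance distributions are
  compared with Welch's t-test by default — the two groups have no reason
  to share a variance — with the pooled-variance variant available and
  reported in verbose mode.

## Metabolic motifs

Within a pathway's reaction graph (directed edges substrate → product,
labelled by promoting KOs), a *motif* is a simple chain of consecutive
reactions of length ≥ 4 with ≥ 3 enriched reactions and at most one
non-enriched. `find_motifs()` enumerates chains depth-first, pruning on
the non-enriched budget, and by default reports only *maximal* chains —
those that cannot be extended at either end without repeating a reaction
or exceeding the budget. Maximality avoids flooding the report with every
sub-chain of one long run; `maximal = FALSE` restores full sub-chain
enumeration. Edges are traversed as drawn; `undirected = TRUE` also
traverses reactions in reverse for reversible-reaction analyses.

Significance multiplies binomial transition terms along the chain. With
p the fraction of the pathway's reactions promoted by an enriched KO, the
step into compound c contributes C(n, y) pʸ (1−p)ⁿ⁻ʸ, where n counts the
reactions incident to c *excluding the chain's previous reaction* and y
counts the enriched ones among them. Because n is defined by exclusion of
a previous reaction, the first reaction has no natural term and is
excluded by default; `include_first = TRUE` adds one using all reactions
at its substrate compound. The printed form of the statistic is the point
mass, which is the default; `mode = "tail"` substitutes P(Y ≥ y) for
users who want a conventional tail at each step. Both choices are
recorded in the report. The reporting threshold (default 0.05) only
flags motifs — all mined motifs are emitted with their p-values.

# The synthetic-data generator

`synth_config()` + `generate_universe()` + `generate_metagenome_pair()`
emulate the statistical structure the analysis assumes, at study scale:

* 148 pathways (the size of the KEGG metabolic-pathway collection), each
  with 5–30 member KOs from an 800-KO pool and 2–6 substrate/product
  compounds from a 300-compound shared pool — the sharing density yields
  a connected network of roughly a thousand edges.
* Background KO abundances are log-uniform over three decades, mimicking
  the heavy-tailed abundance spectrum of real metagenomes.
* 200,000 background reads versus a 2,000-read viral set. In the superset
  design the viral reads are sampled *from* the background reads without
  replacement (exponential-race weighted sampling), so unplanted KOs
  follow the hypergeometric null exactly and planted KOs are
  fold-weighted (default fold 20).
* Planted KOs are drawn with background weights in the top abundance
  decade. This is the generator's stated detectable-effect convention: at
  these depths a fold-20 enrichment of a rare KO (expected viral count
  below one read) is undetectable by any method, so planting it would
  only measure read depth, not the pipeline. Two focus pathways receive
  three planted member KOs each, mirroring the clustering of auxiliary
  genes in nucleotide-metabolism pathways; remaining plants are scattered.
* E-values are log-uniform over 10⁻²⁰…10⁻³ and identities uniform over
  50–100, so a fixed, known fraction of records fails each quality
  filter. A tenth of the viral reads are wrapped into `aa90_` clusters of
  size 2–4; members of a cluster share their quality values (they stand
  for near-identical sequences), which makes cluster expansion exactly
  invertible and keeps the superset invariant intact at the record level.
* Everything is deterministic under the seed (`withr::with_seed`
  internally, so the caller's RNG stream is untouched), and
  `write_synth_bundle()` emits the exact file dialects the readers
  consume, plus a JSON manifest of the configuration.

What the generator does **not** emulate: sequences (no FASTA/FASTQ — the
pipeline starts at annotations), taxonomic composition, correlated KO
abundances within genomes, assembly chimeras, or annotation biases that
depend on read length. Passing tests on synthetic data therefore
demonstrate statistical correctness of the pipeline under its sampling
model, not robustness to those real-data pathologies; the quality filters
exist precisely because real annotations violate the model in ways the
generator does not reproduce.

# Validation problem sizes and numerical choices

The test suite validates each statistical core against an independent
oracle: hypergeometric tails against exhaustive draw enumeration (all
populations up to N = 12), Fisher against the margins identity and
`fisher.test` on random tables, the exact mHG p-value against
exhaustive-permutation enumeration (every binary vector up to length 10)
plus the standard bounds s ≤ p ≤ s·n on 10⁴ random vectors, motif mining
against an independent exhaustive depth-first enumerator (200 random
graphs of up to 12 reactions), network construction against an O(n²)
pairwise check, BFS shells against Floyd–Warshall, and parameter recovery
on 50 generator seeds at the default study scale (sensitivity ≥ 95 % for
fold-20 plants; per-seed false positives within the binomial(m, 10⁻⁴)
99.9 % envelope).

Numerical notes: hypergeometric tails are computed in log space via
`phyper`; the mHG dynamic program counts lattice paths in double
precision, which is exact well past the ~150-node networks this package
targets (overflow would require vectors of length ≈ 1000); rejection-
region membership uses a relative tolerance of 10⁻⁹ to absorb roundoff
in tail recomputation; all rank and report orderings break ties
lexicographically so repeated runs are byte-identical, a property the
pipeline test asserts on full output directories.

# Known limitations

* The published network-level numbers for the real datasets (degree
  means, path-length means, the mHG p-value at the published cutoff, the
  count of significant motifs) depend on the 2012-era KEGG compound sets
  and the GOS/Line-Islands annotations; they cannot be recomputed from
  this package's shipped data and are not claimed by it. The shipped
  published table supports only the score-consistency validation.
* `check_score_consistency()` requires the held-out row to be
  identifiable from the chosen sources; rows whose KOs appear nowhere
  else can only be checked as a group sum.
* The motif p-value treats transition terms as independent, as the chain
  statistic is defined; overlapping chains in dense graphs share terms
  and their p-values are correlated — the report flags, but does not
  correct across, motifs.
* The mHG dynamic program assumes an unweighted ranking; weighted or
  partially-ordered rankings (beyond tie averaging) are out of scope.
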