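Package: auxmet
Title: Enrichment of Host-Like Metabolic Ortholog Groups in Viral Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-metagenomic pipeline for detecting host-like
    metabolic ortholog groups (KEGG Orthologs) that are statistically
    over-represented in marine viral metagenomes, either against a background
    superset (hypergeometric test) or against a paired microbiome (Fisher
    exact test).  Enriched ortholog groups are mapped onto pathway
    definitions and scored with a pathway enrichment score; pathways are
    placed in a compound-sharing global metabolism network for degree,
    minimal-hypergeometric (mHG) ranked-list and path-length-shell analyses;
    and per-pathway reaction graphs are mined for "metabolic motifs" --
    chains of consecutive reactions dominated by enriched ortholog groups --
    scored with a binomial chain statistic.  A seeded synthetic-data
    generator emulates the annotation tables, pathway universe and reaction
    graphs of a marine metagenome study so that the full pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
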