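Package: ptpscan
Title: Motif-Anchored Detection and Catalytic Classification of Classical
    Protein Tyrosine Phosphatase Domains
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico analysis of classical (Class I soluble)
    protein tyrosine phosphatase (PTP) repertoires in insect proteomes, built
    around the Aedes aegypti gene family.  A degenerate-pattern grammar over
    the four active-site motifs (KNRY loop, WPD loop, P-loop/HCX5R, Q loop)
    decides catalytic competence of individual motifs; a motif-constellation
    scanner locates well-formed and degenerate PTP domains in full-length
    proteins; gene-level summaries reproduce repertoire counts including
    pseudophosphatases and curated exclusions.  Companion stages provide
    pairwise global alignment percent identity, neighbor-joining trees with
    Newick/PHYLIP output, efficiency-corrected delta-delta-Ct relative
    expression with classical significance tests, and a fully seeded
    synthetic-data generator (planted-domain proteomes, sequence families on
    known trees, qPCR and egg-count tables) so every stage is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
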