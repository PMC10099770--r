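Package: dock1433
Title: Ranking Candidate 14-3-3 Docking Phosphosites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prioritizes phosphorylated Ser/Thr residues on client proteins
    by their likelihood of mediating 14-3-3 binding. Integrates a normalized
    mass-spectrometry observation-frequency score (PTM score), per-residue
    intrinsic-disorder scores, and consensus-motif sequence scores in a
    random-forest ranker with four output columns (all features, PTM+disorder,
    sequence-only, and an adapted consensus average). Includes leave-one-
    protein-out and repeated-holdout validation with top-k% rank-hit metrics,
    a non-canonical-site analysis, Welch-test feature enrichment, and a
    seeded synthetic-data generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
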