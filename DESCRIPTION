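Package: primertax
Title: Degenerate 16S Primer Coverage Evaluation and Parsimony-Constrained Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico evaluation and optimization of degenerate PCR primers
    against taxonomically annotated 16S rRNA reference sets. Implements IUPAC
    ambiguity-code algebra, a ProbeMatch-style degenerate matcher with amplicon
    simulation, per-rank taxonomic coverage tables and primer-pair comparisons,
    a parsimony-constrained degeneration search that widens a base primer to
    cover a target clade without losing global coverage (the procedure behind
    the Pro341FB variant of Pro341F), a prevalence miner for per-sample
    taxonomic abundance profiles, and deterministic synthetic reference-set and
    profile generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
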