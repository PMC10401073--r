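Package: mitoscreen
Title: Mitochondrial DNA Somatic Variant Filtering and Pooled CRISPR Screen
    Fitness Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two analyses used in studies of tumor mitochondrial
    biology. The first calls and filters somatic mitochondrial DNA (mtDNA)
    heteroplasmies from tumor/normal variant tables and pileups, classifies
    their protein-level effects and OXPHOS-complex membership on the circular
    16,569 bp mitochondrial genome, validates calls against RNA-seq pileups,
    scans per-base coverage for large heteroplasmic deletions, and summarizes
    a tumor cohort. The second scores pooled CRISPR knockout dropout screens:
    counts-per-million log2 normalization, per-guide Z-scores of log2
    fold-change against a reference day, gene-level differential fitness
    (delta-Z between a tumor and a control cell line), and strict-threshold
    hit calling. A seeded synthetic-data module simulates binomial
    heteroplasmy pileups, Poisson coverage with planted deletions, and
    multinomially sequenced screen count trajectories under exponential
    growth with per-gene fitness effects, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
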