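Package: g4cons
Title: Conserved G-Quadruplex Motifs in Promoter Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and cross-species analysis of G-quadruplex (G4) motifs
    in 1000-bp promoter regions. Implements a constrained pattern scanner
    (four G-tracts of three or more guanines, loops of 1-30 nt, total span at
    most 45 nt) on both strands, reliable local block alignments over promoter
    sets, interval-intersection clustering of motif coordinates within
    alignment columns, calling of conserved G4 groups by shared G-tract
    columns, consensus-based substitution counting in loops and tracts with
    matched motif-free controls, and paired Wilcoxon signed-rank inference
    with Holm-Bonferroni correction. A promoter-evolution simulator with full
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
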