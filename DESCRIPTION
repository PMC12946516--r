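Package: homeobias
Title: Homoeolog Expression and Chromatin Bias Analysis for Allotetraploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for homoeolog-resolved analysis of allotetraploid genomes:
    iterative reciprocal-best-hit pairing of homoeologous genes into dyads,
    per-tissue homoeolog expression bias (HEB) and dominance classification,
    expression-variability (CV) and stability (CMD decile) classification,
    H3K4me3 chromatin bias (HPHB) from fold-enrichment tracks, statistical
    comparison of these metrics between structurally rearranged and
    non-rearranged genomic regions, and window-based read-depth utilities for
    addition-line chromosome assignment and centromere midpoint detection.
    Includes a full synthetic-data generator for a two-subgenome (M/U)
    tetraploid so the entire pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
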