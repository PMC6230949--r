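Package: radmap
Title: Pseudo-Testcross Linkage Mapping, Scaffold Anchoring and
    Recombination Landscapes from RAD-Seq Genotypes
Version: 0.1.0
Authors@R:
    person("radmap", "developers", email = "radmap@example.org",
           role = c("aut", "cre"))
Description: Builds F1 pseudo-testcross genetic linkage maps from
    RAD-seq style genotype evidence (two-point recombination fractions,
    LOD scores, Haldane map distances), anchors and orients genomic
    scaffolds into chromosome pseudomolecules (AGP 2.1), and derives
    Marey-map recombination-rate landscapes with hotspot/coldspot calls
    and gene-density association.  Ships a seeded synthetic-cross
    generator (fragmented multi-chromosome genome, planted crossover
    landscape, per-genotype read depth, error and missingness) with full
    ground truth, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
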