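Package: scphylosig
Title: Phylogenetic Signal Extraction and Testing for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("scphylosig", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to extract phylogenetic signal from single-cell RNA-seq
    experiments with many regional samples and heavy dropout. Expression
    counts are standardized per gene and discretized into a five-level
    ordinal character alignment using highest density intervals; per-cell
    consensus bases at candidate SNV sites yield a nucleotide alignment;
    greedy stepwise and quota-based selection filters raise data density;
    and phylogenetic clustering of sample groups on reconstructed trees is
    tested with mean pairwise distance (MPD) and mean nearest taxon
    distance (MNTD) permutation statistics, with Benjamini-Hochberg false
    discovery rate control and summarization over bootstrap or posterior
    tree samples. A tree-structured synthetic-data generator emulating a
    multi-sample tumor/circulating-cell design with uneven per-cell
    dropout makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
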