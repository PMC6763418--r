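Package: redalph
Title: Comparing and Combining Reduced Amino-Acid Alphabets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing and combining simplified (reduced) amino-acid
    alphabets. Each alphabet is a partition of the 20 standard amino acids into
    groups of mutually similar residues. The package encodes alphabets as
    binary intra-group co-membership matrices, scores pairwise alphabet
    similarity over the 380 informative matrix cells, combines collections
    into consensus amino-acid similarity and distance matrices, builds
    unrooted dendrograms by neighbor joining with ordinary-least-squares
    branch-length refinement, quantifies tree stability by leave-one-out
    jackknifing with the branch score distance, derives nested simplified
    alphabets by agglomerative clustering of the consensus, and tests the
    agreement of two amino-acid distance matrices with a row-order
    randomization (Mantel-style) null distribution and a principal components
    view of alphabet space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
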