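Package: lmsclust
Title: Alignment-Free Classification of Multi-Domain Proteins via Local Matching Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters protein sequences without alignment. Pairwise distances
    are derived from Local Matching Scores (LMS): BLOSUM62 diagonal scores are
    summed over residues covered by five-residue fragments shared exactly
    between two sequences, then normalized to a distance in [0, 1]. The
    distance matrix is subjected to Ward's minimum-variance hierarchical
    clustering; the dendrogram can be exported as Newick and parsed into flat
    clusters at a cut-off in [0, 1]. Per-cluster domain-architecture
    similarity is reported with the Jaccard index, the rescaled
    Goodman-Kruskal gamma and a duplication-similarity index. Also included:
    a Robinson-Foulds comparator for trees on the same leaf set and a
    synthetic multi-domain protein family generator (point substitutions,
    domain-order shuffling, circular permutation) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
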