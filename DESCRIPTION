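Package: pocketsim
Title: Alignment-Free Similarity Metrics for Protein Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds fixed-length vector representations of protein-ligand
    binding sites by pooling per-residue sequence-embedding vectors over the
    pocket interface residues identified with a radially truncated Voronoi
    tessellation around the ligand. The Euclidean metric on these pocket
    vectors drives downstream machinery: agglomerative clustering with a
    strictly enforced minimum separation between clusters, optimal-transport
    comparison of clusterings via best-match Jaccard assignment, a minimum
    spanning tree "pocket atlas" over clusters, Moran's I spatial coherence
    statistics with permutation nulls, and debiased train/test split
    generation (cluster-based and tree-based) for pocket-centric machine
    learning, illustrated with a per-residue ligandability classifier.
    Includes a deterministic mock embedder and a synthetic-complex generator
    with planted interface ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    boot,
    clue,
    igraph,
    nnet,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
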