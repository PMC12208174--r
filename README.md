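# pocketsim

Alignment-free similarity metrics for protein–ligand binding sites, with
the downstream machinery that a pocket-centric analysis needs: clustering
with enforced separation, optimal-transport comparison of clusterings, a
minimum-spanning-tree "pocket atlas", spatial coherence statistics, and
debiased train/test splits for machine-learning benchmarks.

## The problem

Comparing binding sites is central to target discovery, ligand transfer,
selectivity analysis and the honest benchmarking of pocket-centric ML
models. Alignment-based structural metrics are accurate but expensive, and
sequence-identity cutoffs are a poor stand-in for 3D similarity when
building train/test splits — near-identical pockets on proteins with < 20%
sequence identity slip straight through a homology filter and reward
memorization.

`pocketsim` represents a pocket as a fixed-length vector built in three
steps:

1. **Interface extraction.** A radially truncated Voronoi tessellation is
   computed over the union of protein and ligand heavy atoms. A protein
   atom is in contact with a ligand atom iff their Voronoi cells share a
   facet *and* their distance is at most a truncation radius *r* (default
   6 Å); a residue is an interface residue iff one of its atoms is in
   contact. The facet condition removes buried residues that a plain
   distance cutoff would include.
2. **Per-residue embedding.** A pluggable embedder maps the full chain
   sequence to an L×D matrix of per-residue vectors. A deterministic mock
   embedder (64-bit hashing, no model download) ships with the package;
   a real protein language model plugs in through the same
   `embedder_spec()` adapter interface.
3. **Pooling.** The pocket vector is the arithmetic mean of the embedding
   rows at the interface positions; pocket–pocket distance is Euclidean:
   d(a, b) = ‖v̄ₐ − v̄ᵦ‖₂ with v̄ = (1/|I|) Σᵢ∈I xᵢ.

On top of the metric:

* `cluster_single_linkage(D, t)` — the partition whose clusters are the
  connected components of the d < t graph; every cross-cluster pair is at
  distance ≥ t (a structural separation guarantee).
* `ot_cluster_similarity(A, B)` — best one-to-one matching of clusters by
  Hungarian assignment on the Jaccard matrix; average matched Jaccard,
  with a scrambled-label null (`scrambled_null()`).
* `build_mst()` / `export_graph()` — the pocket atlas: an MST over
  clusters weighted by minimum distance of approach, exportable to
  GraphML for layout tools.
* `morans_i()` — spatial coherence of per-cluster annotations, with a
  permutation null (analytic mean −1/(n−1)).
* `cluster_split()` / `tree_split()` / `validate_split()` — debiased
  train/test splits from whole clusters or whole MST branches, with
  leakage counting.
* `label_residues()` / `train_residue_classifier()` / `evaluate_auc()` —
  a per-residue ligandability harness (binary contact labels at 4 Å,
  single-hidden-layer MLP on embedding rows, tie-aware ROC-AUC).
* `generate_synthetic_complex()` and friends — synthetic complexes with
  planted interface ground truth, buried decoys, pocket families and a
  hierarchically structured split benchmark, used throughout the tests.

## Worked example

Thirty synthetic complexes in three planted pocket families, end to end:

```r
library(pocketsim)

fam <- generate_pocket_families(n_complexes = 30, n_families = 3,
                                n_residues = 40, seed = 1)
spec <- embedder_spec("mock", dim = 32)
pockets <- lapply(fam$truths, function(tr) {
  ifc <- compute_interface_residues(tr$complex, 6.0)
  emb <- embed_sequence(tr$complex$sequence, spec,
                        complex_id = tr$complex$complex_id)
  pool_pocket_embedding(emb, ifc, pocket_id = tr$complex$complex_id)
})
D <- pairwise_distances(pockets)
t_star <- choose_threshold(D)        # largest jump in MST merge heights
C <- cluster_single_linkage(D, t_star)
planted <- structure(list(ids = fam$ids, labels = fam$family - 1L,
                          t = 0, n_clusters = 3),
                     class = "pocket_clustering")
ot_cluster_similarity(C, planted)
tree <- build_mst(cluster_min_distances(D, C))
sp <- cluster_split(C, 0.3, seed = 1)
validate_split(sp, D, t_star)
```

Output:

```
chosen threshold: 1.071
<pocket_clustering> 30 pockets in 3 clusters at t = 1.071014
  cluster sizes: 10,10,10
<ot_comparison> similarity = 1
  matched cluster pairs: 3
<pocket_tree> 3 clusters, 2 edges, total weight 3.011
<split_spec> cluster split: 20 train / 10 test (33.3% test)
<leakage_report> 0 train-test pairs below t = 1.07101 (min cross distance 1.3751)
```

Reading it: the threshold picked from the distance distribution recovers
the three planted families exactly (OT similarity 1.0 against the planted
partition), the atlas links the three clusters with two MST edges, and the
cluster-based split has zero train–test pairs closer than the clustering
threshold — the separation guarantee at work. The minimum train–test
distance (1.38) exceeds the threshold (1.07).

A thin command-line wrapper over the same functions is installed at
`inst/cli/pocketsim.R` (subcommands `ligands`, `extract`, `interface`,
`pocketvec`, `dist`, `cluster`, `compare`, `atlas`, `split`, `validate`,
`label`); run it with `Rscript` and `--help`-style headers in the file.

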