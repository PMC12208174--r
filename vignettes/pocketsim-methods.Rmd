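---
title: "Methods: pocket representations, clustering with enforced separation, and debiased splits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket representations, clustering with enforced separation, and debiased splits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketsim)
```

## The model

A binding site is represented by the residues lining it. `pocketsim`
builds a pocket vector in three steps — interface extraction, per-residue
embedding, mean pooling — and all downstream machinery (clustering, the
atlas, splits, the druggability harness) operates on Euclidean distances
between these vectors.

### Interface extraction by radially truncated Voronoi tessellation

Given the heavy atoms of one protein chain (or a concatenation of chains)
and the heavy atoms of one ligand, consider the Voronoi diagram of the
union point set. A protein atom and a ligand atom are *in contact* iff

1. their Voronoi cells share a facet, and
2. their Euclidean distance is at most the truncation radius $r$.

A residue is an interface residue iff at least one of its atoms is in
contact. The facet condition is what distinguishes the tessellation from
a plain distance cutoff: an atom that sits within $r$ of the ligand but
*behind* the first shell has its potential facet blocked by the
intervening atom, and is excluded. The truncation suppresses the spurious
long-range facets that unbounded Voronoi cells otherwise produce.

The facet test is exact, not approximate. Cells of points $a, b$ share a
positive-area facet iff some point $x$ on their bisector plane is strictly
closer to them than to every other point $k$, i.e. iff the linear program

$$\max s \quad \text{s.t.}\quad 2(p_k - p_a)\cdot x + s \le \lVert p_k\rVert^2 - \lVert p_a\rVert^2
\;\;\forall k,\qquad 2(p_b - p_a)\cdot x = \lVert p_b\rVert^2 - \lVert p_a\rVert^2$$

has a strictly positive optimum ($s$ is an empty-sphere margin in squared
Ångström, capped at 1 so the program is bounded; coordinates are centred
on the pair's midpoint for conditioning). The LP is solved with the
simplex implementation in the recommended `boot` package, once per
candidate pair (ligand–protein pairs within $r$), so cost scales with the
interface, not with the structure. The unit tests check this production
path against an independent brute-force oracle — enumeration of
empty-circumsphere tetrahedra — and the two agree exactly on general-position
inputs.

**Degenerate geometry.** Coplanar point sets (detected by a singular-value
check) raise a classed error rather than being silently jittered; the
distance-only mode is the documented fallback. This favours
reproducibility over convenience.

**Defaults.** Truncation radius 6 Å (a conventional Voronoi-contact
truncation in interface analysis), heavy atoms only, no facet-area filter
(the facet condition is binary and parameter-free). All are exposed as
arguments.

### Per-residue embeddings and the mock embedder

Embeddings are always computed on the **full chain sequence** and then
indexed by interface positions — never on the interface subsequence —
because each row should carry global sequence context. An external
protein language model plugs in through `embedder_spec(kind =
"external-plm", fun = ...)`, which must return the model's final-layer
per-residue rows with special tokens stripped; a missing adapter raises
an error and is never silently replaced by the mock.

The built-in mock embedder makes the whole pipeline deterministic and
dependency-free: component $k$ of residue (letter $a$, position $p$) is
the 64-bit FNV-1a hash of the byte triple $(a,\ p \bmod 64,\ k)$, passed
through a Murmur3-style finalizer (xor-shift/multiply rounds) and scaled
to $[-1, 1]$. The finalizer matters: over 3-byte inputs, raw FNV-1a
output bits barely avalanche — neighbouring $(p, k)$ cells correlate at
$\approx 1$, which collapses pooled vectors of unrelated pockets to
near-identity. With the finalizer, cells are decorrelated and pooled
vectors of disjoint interfaces sit at the expected chance distance. The
hash is implemented in exact 16-bit limb arithmetic (all intermediates
below $2^{53}$), so the matrix is bit-identical across IEEE-754
platforms and was verified against an independent implementation. An
optional window parameter averages rows over $p-w..p+w$ to give the mock
weak context sensitivity.

The mock embedder is a *structural* stand-in: it preserves exactly the
properties the pipeline relies on (determinism, letter and position
sensitivity, fixed dimension) and none of the biology. Tests passing on
mock embeddings validate the machinery around the embedder, not the
biological quality of any particular language model.

### Pooling and the metric

The pocket vector is the arithmetic mean of the interface rows; the
pocket–pocket distance is Euclidean. Min–max normalization
(`minmax_normalize`) linearly maps off-diagonal distances onto $[0,1]$
for cross-metric comparisons and preserves all rank orderings; the
native→normalized threshold map is retained so thresholds can be quoted
on either scale.

The baseline sequence distance is $1 - \text{identity}$ under global
(Needleman–Wunsch) alignment with BLOSUM62 and affine gaps (open 10,
extend 0.5), where identity counts identical columns over the full
alignment length *including terminal gaps* — the EMBOSS Needle
convention. Biostrings clips terminal gaps from its aligned strings, so
the implementation adds the unaligned overhang back explicitly; an
exhaustive small-case alignment enumerator in the tests pins this down.

The onset/global correlation analysis (`onset_correlation`) compares two
metrics over the same pocket pairs: the *onset* region contains pairs
below either metric's maximum clustering threshold (strictly below —
boundary pairs are excluded), and Spearman rank correlation (average-rank
ties) is reported on that subset and globally. Fewer than three onset
pairs yields `NA`, never a fabricated zero. Pair vectors are serialized
in a documented order (row-major upper triangle of the id-sorted matrix)
so two metrics align pair-for-pair.

## Clustering with a strict minimum separation

The partition at threshold $t$ is the set of connected components of the
graph with an edge wherever $d < t$. This is exactly the single-linkage
cut, and it is implemented as union-find over the $\varepsilon$-graph
rather than as a dendrogram-library call so the defining guarantee —
**every cross-cluster pair is at distance $\ge t$** — holds by
construction, with strict $<$ for merging (at $d = t$ exactly, pockets
stay separated). $t = 0$ gives all singletons. Labels are canonicalized
by smallest member index, making outputs byte-stable. Tests verify
equivalence against `igraph` connected components on random matrices,
exhaustive cross-cluster separation, and nestedness across thresholds.

### Comparing clusterings by optimal transport

Two partitions of the same pockets are compared by building the Jaccard
matrix over cluster pairs and solving the assignment problem that
maximizes total Jaccard (Hungarian algorithm via `clue::solve_LSAP`).
The similarity is the matched total divided by $\max(K_A, K_B)$:
unmatched clusters contribute zero, and identity is the unique maximizer.
(The alternative "matched" denominator is exposed as a flag; with cluster
counts matched between the two partitions, as in typical protocols, the
choice is inert.) Singleton exclusion removes size-1 clusters from both
partitions *and their members from the other side* before matching.

The scrambled null retains cluster sizes while reshuffling pocket labels
uniformly; the reported null is the mean over scrambles (default 100,
seeded). Whether such a null should average over replicates or report a
single scramble is underdetermined; averaging gives a stable reference
value. Tests check the exact exhaustive-permutation expectation at
$n = 8$ within Monte-Carlo error.

## The pocket atlas

Cluster-level distances are minima of approach ($\min_{a \in A, b \in B}
d_{ab}$); the atlas is the minimum spanning tree of the complete cluster
graph under these weights, built with Kruskal's algorithm and a
deterministic lexicographic tie rule. 2D layout is deliberately out of
scope: the tree exports to GraphML (with cluster sizes and arbitrary
annotation columns) for external layout or network tools.

Spatial coherence of a per-cluster annotation is measured by Moran's I,

$$I = \frac{n}{W}\,\frac{\sum_{i\neq j} w_{ij}\,(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2},$$

with weights either $1/d_{ij}$ (inverse distance, default) or 1 on MST
edges. The null is estimated from uniform permutations of the values; its
analytic mean $-1/(n-1)$ anchors the permutation test in the suite.
Categorical annotations are analysed per category (one-hot), reported
separately. When inter-cluster distances are nearly uniform the
inverse-distance weights have little contrast and the MST-adjacency
scheme is the more sensitive choice; both are exposed.

## Debiased train/test splits

Two constructions, both operating on whole clusters so that no pair of
near-duplicate pockets straddles the split:

* **Cluster-based**: clusters are shuffled (seeded) and assigned to the
  test side until the test pocket count first reaches the target
  fraction (overshoot allowed — sizes need only be approximately
  constant). At $t = 0$ this reduces to a plain random split. If a
  single cluster exceeds the feasible size the returned split is flagged
  `infeasible`, never silently fixed by breaking a cluster.
* **Tree-based**: entire MST branches are detached; each cut edge
  $(u, v)$ removes the side containing $v$, sequentially on the
  shrinking remainder. `suggest_branch_cut()` scans edges for the branch
  closest to a target fraction.

`balance_to_size()` moves whole clusters greedily toward a target test
fraction (±5% band), ties broken by smallest cluster label;
`validate_split()` counts train–test pairs below a threshold. A split
built from clusters at threshold $t$ always validates clean at that $t$
— a structural consequence, verified over random instances. Note that
with sequential branch removal the train side always retains the last
cut's parent node, so the "all clusters removed" error state is a
defensive guard rather than a reachable outcome of valid cut sequences.

## The per-residue ligandability harness

Residue labels are binary ligand contact: 1 iff any heavy atom of the
residue is within 4 Å of any ligand heavy atom (a conventional
heavy-atom contact cutoff, deliberately distinct from the 6 Å
tessellation truncation; both exposed). The classifier is a
single-hidden-layer perceptron (`nnet`; default 8 hidden units, 300
iterations, weight decay 0.1, inverse-frequency class weights — sized
for the small synthetic harnesses this package ships and trains in
seconds) on per-residue embedding rows, trained strictly on the
train-side complexes of a split. Evaluation pools all residues of the
requested side and reports the rank (Mann–Whitney) ROC-AUC, which
handles score ties by average ranks and is invariant under monotone
transforms; it is cross-checked against `pROC` in the tests. Multi-layer
architectures were not pursued: the harness exists to compare *splits*,
not to maximize absolute AUC, and a one-layer MLP already separates the
synthetic signal cleanly.

## The synthetic study conditions

The generators define the conditions under which the package validates
itself; they emulate the geometry and statistics the method cares about
and nothing else.

**Planted complexes** (`generate_synthetic_complex`): an idealized
α-helix (CA radius 2.3 Å, rise 1.5 Å, 100°/residue — CA–CA spacing
≈ 3.8 Å) with one outward CB pseudo-atom per residue; ligand atoms are
placed 2.5 Å outside the CBs of the requested interface residues (tilted
off-radial so the inward ray clears the backbone). Helix geometry then
guarantees all other residues stay > 6 Å from the ligand. *Buried
decoys* receive a side-chain atom placed on the segment from a ligand
atom through a first-shell CB, beyond it: within the radius but occluded.
The decoy is jittered only **along** the ray — an exactly collinear
strictly-between blocker defeats every empty sphere through the
endpoints, whereas a lateral offset lets the sphere's center escape
sideways, which is also why real buried atoms just off a shell atom's
shadow can legitimately remain in tessellation contact. All distance
constraints are re-verified by an all-pairs check before a complex is
returned; generation is deterministic per seed with bounded retries.

**Pocket families** (`generate_pocket_families`): each family has its own
base sequence and its own interface-position set (families' sets are
drawn jointly without replacement, so they are disjoint — families model
distinct pockets, not variants of one site); members differ by a single
substitution at one designated interface position. Any two members then
differ in exactly one pooled row (within-family distance ≈ ‖Δrow‖/K)
while across-family vectors are means of disjoint hash rows (distance
≈ √(2D·Var/K)), a √K-fold margin that makes exact family recovery the
expected outcome, not a tuned one.

**Split benchmark** (`generate_split_benchmark`): complexes belong to
families nested in superfamilies. Contact residues are shifted along a
signal direction that decomposes into exactly orthonormal shared,
superfamily and family components (magnitudes 0.5 / 1.5 / 2.0, Gaussian
row noise 0.7, 40 residues per complex, 30% contact fraction, dimension
24). Orthonormality makes the planted separations deterministic:
within-family pocket distance ≈ 1.6, family gap ≈ 3.3, superfamily gap
≈ 3.9, so clustering at t = 2.4 recovers families and the MST groups
superfamilies. A classifier evaluated across a random split can exploit
family directions (leakage), across a cluster split only superfamily and
shared ones, across a branch split only the weak shared one — producing
the expected hardness progression of test AUCs without any claim about
absolute values on real data.

**What this does and does not show.** Synthetic complexes have two atoms
per residue, ideal-helix geometry and hash embeddings; real pockets have
side-chain flexibility, crystal-contact artefacts, nonstandard residues
and embedders whose similarity structure reflects biology. Passing tests
demonstrate the correctness of the tessellation, metric, clustering,
atlas, split and harness *machinery* and the qualitative split-hardness
phenomenon; they say nothing about the biological fidelity of any
particular embedding model on experimental structures.

## Numerical choices and edge cases

* LP facet margin: strict-positivity tolerance $10^{-7}$ (squared Å) with
  cap 1; midpoint centring for conditioning. General-position inputs give
  margins orders of magnitude away from the tolerance.
* `choose_threshold`: the largest jump in sorted single-linkage merge
  heights (equivalently, MST edge weights), not in raw pairwise
  distances — raw-distance gaps are dominated by sparse tails.
* Kruskal tie-break: (weight, then lexicographic (u, v)); byte-stable
  trees under equal weights.
* Altloc resolution: highest occupancy wins, ties toward blank/'A', with
  the original file order of atoms restored afterwards.
* Strict `<` everywhere a threshold defines membership (cluster merging,
  onset region, leakage counting); boundary pairs fall on the separated
  side.
* Problem sizes in the validation suites (50 planted complexes for the
  tessellation oracle, 100 random matrices up to n = 300 for clustering,
  5 seeds × 60 complexes for the hardness progression, 2000 scrambles
  against an exhaustive n = 8 null) were chosen so the full suite runs in
  about a minute on one core while keeping every Monte-Carlo comparison
  inside three standard errors of its exact reference.

## Known limitations

* PDB only (no mmCIF); single selected ligand per complex; multimeric
  interfaces are handled by a best-contacting-chain default or explicit
  chain concatenation — per-chain embedding with cross-chain pooling is a
  documented choice, untested against a reference treatment.
* The LP facet test solves one simplex per candidate pair with all atoms
  as constraints; for very large structures a spatial prefilter of
  constraint atoms would be the next optimization.
* The external-PLM adapter is an interface, not a bundled model; nothing
  in this package validates a specific language model.
* Homology-based splits are accepted as external id lists, not computed.
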