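---
title: "Contrastive 2D maps of antibody repertoires: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive 2D maps of antibody repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

abmapr turns tables of antibody (or BCR nucleotide) sequences into 2D maps
on which clonal families appear as tight, well-separated clusters. This
vignette explains the model and every consequential design choice; the
README shows a worked example.

## The problem

B-cell receptors diversify by V(D)J recombination and somatic
hypermutation, producing clonal families: sets of sequences descending from
one rearrangement, typically differing by a handful of point mutations.
Identifying these families in repertoires of 10^4–10^6 sequences — often
without usable germline references (camelids, rabbits, synthetic and
ML-generated libraries) — is the core task this package addresses. The
approach is annotation-free: relatedness is inferred from the sequences
alone.

## The model

Three trainable parts compose the projection:

1. **Sequence encoder** `f: x -> e ∈ R^d` — a small BERT-style masked
   language model (token + position embeddings, multi-head self-attention,
   GELU feed-forward, post-layer-norm), pretrained on the input repertoire
   itself with the standard masking recipe (15% of residue positions;
   80/10/10 masked/random/kept). Pooling is a mean over non-pad token
   states, so any admissible sequence maps to a fixed-size vector
   (`embed_dim`, default 256; desk-scale analyses and the test-suite use
   16–64). The transformer, its backward pass, and Adam are implemented
   directly in R; gradients are verified against finite differences in the
   test suite. Any external embedding function can be plugged in via
   `external_encoder()` (it is then not fine-tuned).

2. **Linear transform** `R^d -> R^d`, and

3. **Projection head** `R^d -> R^2`, both linear.

### Neighbor structure

Positive pairs come from sequence space, not from augmentation: two
sequences in a length-homogeneous group are *neighbors* when their
full-sequence Hamming distance is at most `full_cutoff` (default 5) **and**
each non-empty CDR3 differs by at most `cdr3_cutoff` (default 2). Both
bounds are inclusive; for paired chains the CDR3 constraint applies to
HCDR3 and LCDR3 independently. `adaptive_cutoff()` instead scans cutoffs
upward until a target mean neighbor count (5–10 is a good range) is
reached, coupling the CDR3 cutoff as `ceiling(0.4 * full_cutoff)` to
preserve the default 2/5 ratio. Sequences with fewer than `min_neighbors`
(default 5) neighbors are excluded from training — they are hard to place
and act as background noise. Exclusion is a single pass by default; an
iterate-to-fixed-point mode exists but removes more sequences and is rarely
warranted.

### Loss

For a batch of N anchors `x_i` (drawn with probability proportional to
`log` neighbor count, with replacement; one epoch visits N_kept anchors)
each paired with one uniformly sampled neighbor `x_i'`, squared Euclidean
distances `d11 = |e_i - e_j|^2 + ε` and `d12 = |e_i - e_j'|^2 + ε` are
turned into Cauchy similarities `φ = 1 / (1 + dsq)`. The per-row loss is

    L_i = -log φ_{i,i+N}  +  log Σ_j M_ij φ_ij ,

averaged over rows; the mask `M` zeroes the anchor itself, its sampled
partner, and every in-batch neighbor, so repulsion acts only between
non-neighbors. Options: `normalize_by_counts` divides the positive term by
the in-batch neighbor count and the negative one by the non-neighbor
count; `pos_sum_in_log` switches to the aggregate positive form
`-log Σ_i φ_{i,i+N}`. The package defaults to the per-row form: it is the
form consistent with averaging the loss over rows and with the t-SimCNE
family of objectives, and its gradient treats every anchor equally.

An optional kernel rescales squared distances as `a * dsq^b` before the
similarity, with `(a, b)` least-squares fitted so `1/(1 + a x^{2b})`
matches a target that is 1 below `min_dist` (default 1.0) and decays as
`exp(-(x - min_dist))` beyond (grid `(1e-3, 10·min_dist]`, 300 points).
This preserves attraction at small map distances; the default leaves the
kernel off, which was sufficient for every benchmark here.

Numerical choices: `ε = 1e-6`; rows whose repulsion set is empty contribute
a zero negative term (with a warning) rather than −∞; softmax rows in the
attention are max-stabilized.

### Training schedule

Stage 1 trains the encoder and the linear transform on the contrastive
loss evaluated in the transform's d-dimensional output (the head is not
attached yet); stage 2 freezes both and trains the 2-unit head; stage 3
unfreezes everything at a lower learning rate. Defaults are 400/100/400
epochs with Adam at (1e-3, 1e-3, 1e-4) and batch size 256 (clamped to the
number of kept sequences with a warning). The desk-scale runs used
throughout the tests and the acceptance script use a 32-wide, 1-layer,
2-head encoder, 3 MLM epochs, and 30/30/30 contrastive epochs for the
clonal-family benchmark (15/60/15 for the hierarchical one, whose larger
single group makes encoder stages costlier while the cheap head stage does
most of the layout work): on the simulated benchmarks below the maps
converge well within those budgets on a single CPU in minutes. Stage 1 optimizing in d dimensions (not through a
temporary 2D head) follows the staged design of the contrastive-projection
literature; both behaviors can be obtained by setting stage epochs to zero.

Maps are reproducible given a seed; because the loss only sees pairwise
distances, reproducibility is judged on distance matrices — coordinate
rotations and flips are equivalent maps.

## Clustering and refinement

`leiden_on_map()` builds the undirected union of the directed 20-nearest-
neighbor graph on the 2D coordinates (unit weights) and optimizes
modularity with the Leiden algorithm. **Resolution matters more than k**:
contrastive maps produce elongated, extremely dense family blobs, and
modularity at resolution 1 reliably chops such blobs into 2+ pieces (the
well-known resolution behavior of kNN graphs). Because the mapped
sequences all passed the neighbor filter, distinct families have no
connecting kNN edges at all, so a *low* resolution cannot merge them —
scanning 0.01–0.1 on simulated-lineage maps, every planted family was
recovered exactly at 0.05 and no setting down to 0.01 ever mixed two
families, while 0.1 still split single-family groups. The pipeline default
is therefore `leiden_resolution = 0.05` with `k = 20`; the standalone
`leiden_on_map()` keeps the igraph-conventional default of 1 for generic
point sets.

Sequences excluded from training are still projected with the trained
model and attached to the nearest cluster if they fall within twice the
median 20th-neighbor distance of the clustered points, else they stay
unclustered (−1). Clustering the full projected map instead (noise
included) was evaluated and rejected: at desk scale, random noise
sequences project onto the family blobs and poison the partition.

Cluster refinement (`refine_labels()`) sums the standardized (unit
root-mean-square radius) primary map with a CDR3 feature embedding at
weight 0.3 and re-clusters; with `edge_only = TRUE` only sequences whose
20 map neighbors agree with their own label less than 60% of the time are
re-assigned (to the dominant label among their unambiguous neighbors in
the combined space). The CDR3 features are overlapping 3-mers of the
*generalized* CDR3 — residues collapsed to six physicochemical classes
(positive `KRH`, negative `DE`, aromatic `FWY`, aliphatic `AVLIMC`, polar
`STNQ`, special `GP`) — reduced by PCA to two dimensions with
deterministic component signs.

## Annotations and metrics

Net charge is a Henderson–Hasselbalch sum over ionizable side chains with
EMBOSS-style pKa values, termini off by default (Fv fragments are interior
slices); hydrophobicity is the mean Kyte–Doolittle hydropathy; selection
enrichment is `ln` of the pseudocount-regularized post/pre frequency ratio
with classes enriched (> 0.05), depleted (< −0.05), unclear otherwise.

Benchmark metrics follow pair-counting definitions: precision/recall/F1
over all non-noise pairs (unclustered sequences count as singletons;
counts pooled across length groups before the ratios); cluster types
true-inferred (covers ≥ 80% of some family — coverage only, an optional
purity requirement is off by default), noise (only noise members), or mix;
per-cluster mean pairwise Hamming distance; Shannon entropy (base 2) of
categorical labels; homogeneity as the dominant-class fraction; and the
Pearson (optionally Spearman) correlation between Hamming distance from a
seed sequence and Euclidean distance from its map position.

## The simulators, and what passing them does (not) show

`simulate_lineages()` emulates a somatic-hypermutation benchmark: each
family grows by copying a uniformly chosen existing member with
`Binomial(L, 0.01)` substitutions (defaults: 10 families of 150–250
members, lengths drawn from {90, 96, 102} nt with CDR3 windows of
{15, 18, 21} so at least three length groups arise, plus 2,000 random
singleton noise sequences matching the length design). `simulate_hierarchical()`
grows a seed-rooted designed library the way optimization campaigns do:
substitutions are confined to a pool of 24 designed positions (CDR-window
positions drawn into the pool at 2× weight), each with one designated
alternative residue, and variants extend 20 persistent design lineages —
each new variant inherits its lineage's mutation set and adds/removes pool
mutations to hit an exact edit target, spanning edits 0–11 over ~3,000
amino-acid sequences. Consecutive tiers stay Hamming-connected, same-edit
shells share pool mutations (so the neighbor graph forms concentric
shells, not isolated spokes), and `edit_from_seed` is exact by
construction. The pool structure matters: with substitutions spread
uniformly over all positions instead, the data become intrinsically
high-dimensional and *no* 2D embedding can order them radially (classical
MDS on the full Hamming matrix — an upper bound for global-distance
methods — reaches only r ≈ 0.6 there), which would misrepresent the
designed libraries this benchmark emulates. `simulate_labeled_library()`
plants labelled prototype groups for the cluster-quality metrics.

These generators share the benchmarks' *structure* but are uniform where
real data are not: substitutions are position-uniform apart from the CDR
bias and the design pool, there are no indels, no selection, no sequencing
error, and noise is uniformly random rather than germline-adjacent.
Passing the simulation benchmarks therefore shows the machinery recovers
planted structure under the stated conditions; it does not certify
performance on real repertoires, where alignment quality, indels and
primer artifacts dominate.

## Degenerate inputs and tie-breaks

Duplicate rows are merged before mapping (read counts summed, CDR3
conflicts reported) and results propagate back to every original row.
Hamming distance requires equal lengths and treats alignment gaps as
ordinary symbols (a flag skips gap–gap columns). kd-trees split at the
lower median with ties broken by sequence id, making node membership
independent of input order; consensus ties yield IUPAC codes (nucleotide)
or `X` (amino acid). PCA component signs are fixed by the largest
loading. Empty repulsion sets, all-excluded graphs, unreachable adaptive
targets, and CDR3s shorter than k all degrade with explicit warnings or
advisory errors rather than silent misbehavior.

## Known limitations

The encoder is deliberately small; it adapts to the input repertoire but
is not a general protein language model, and nucleotide tokenization is
per-base (not codon-aware). Training cost scales linearly in sequences ×
epochs × length; the pure-R transformer is adequate to ~10^4 sequences per
group on one CPU but is not a GPU substitute. Variable-length inputs must
be pre-aligned or grouped by length — no internal alignment is attempted.
Leiden resolution defaults are tuned to the kept-only map topology this
pipeline produces; maps made elsewhere may need the igraph-conventional
resolution of 1.
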