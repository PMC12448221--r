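# abmapr — contrastive 2D maps of antibody repertoires

High-throughput sequencing of B-cell receptors produces repertoires of
10<sup>4</sup>–10<sup>6</sup> antibody sequences in which the unit of biological
interest — the clonal family, a set of sequences descended from one V(D)J
rearrangement and diversified by somatic hypermutation — has to be
recovered computationally, often without usable germline references
(camelids, rabbits, synthetic and ML-generated libraries). abmapr infers
relatedness from the sequences alone: it embeds a repertoire into a 2D map
on which clonal families appear as tight, well-separated clusters, then
clusters, annotates, and scores the map.

## The method

1. **Masked-LM encoder.** A small BERT-style transformer `f: x ↦ e ∈ R^d`
   is pretrained on the input repertoire with the standard masking recipe
   (15% of positions, 80/10/10) and mean-pools token states into a
   fixed-size embedding (default `d = 256`). The transformer and its
   backward pass are implemented directly in R and verified against finite
   differences. Any external embedder can be plugged in.

2. **Antibody-aware neighbor graph.** Within a length-homogeneous group,
   `i ~ j` iff the full-sequence Hamming distance ≤ 5 *and* each non-empty
   CDR3 differs by ≤ 2 (both inclusive; cutoffs adaptive on request).
   Sequences with < 5 neighbors are excluded from training.

3. **Contrastive projection.** With anchors `x_i` (sampled ∝ log neighbor
   count) and one sampled neighbor `x_i'` each, squared distances
   `d_ij = ‖e_i − e_j‖² + ε` become Cauchy similarities
   `φ_ij = 1/(1 + d_ij)`, and the per-row loss

   `L_i = −log φ_{i,i+N} + log Σ_j M_ij φ_ij`

   pulls neighbors together while the mask `M` restricts repulsion to
   non-neighbors. Training is staged: encoder + linear transform in `d`
   dims, then a 2-unit linear head alone, then everything. An optional
   fitted kernel `a·d^b` keeps similarity ≈ 1 below a `min_dist` of 1.0.

4. **Clustering, annotation, scoring.** Leiden on the map's kNN graph
   (k = 20, resolution 0.05 — see the vignette for why low resolution is
   right for these maps), optional CDR3 k-mer refinement in a reduced
   physicochemical alphabet, net charge / hydrophobicity / panning
   enrichment overlays, pairwise precision–recall–F1 and cluster-type
   (true-inferred / mix / noise) benchmarking, seed-distance correlation,
   and kd-tree lineage consensus with trajectory alignments.

Simulators for clonal lineages with singleton noise, seed-rooted
hierarchical design sets, and FACS-labelled libraries make every stage
testable end to end without external data.

## Worked example

```r
library(abmapr)

## simulated benchmark: 10 clonal families (~2,000 sequences, per-copy
## mutation rate 0.01, three sequence lengths) plus 2,000 noise singletons
tab <- simulate_lineages(seed = 101)

cfg <- run_config(
  encoder  = encoder_config(embed_dim = 32, n_layers = 1, n_heads = 2,
                            hidden_dim = 64, max_len = 256,
                            alphabet = "nucleotide"),
  mlm_epochs = 3,
  schedule = training_schedule(30, 30, 30, batch_size = 256),
  min_group_size = 50, seed = 101)

run <- run_pipeline(tab, cfg, out_dir = "out",
                    truth_col = "lineage_id", noise_col = "is_noise")
run
#> ab_run: 4063 sequence(s), 6 mapped group(s), config 54375524
#>   precision 1.000 recall 0.998 F1 0.999 | TIC 1.00 mix 0.00 noise 0.00
```

About five minutes on one CPU. The printed numbers are the pooled pairwise
precision/recall/F1 over all non-noise sequence pairs (a pair is a true
positive when its two sequences share both a true family and an inferred
cluster) and the fractions of inferred clusters that are true-inferred
(cover ≥ 80% of a family), mixed, or pure noise. `out/` holds the combined
and per-group map CSVs (`id`, chains, CDR3s, `x`, `y`, `cluster`,
annotations), `metrics.json`, and the resolved `config.json`.

Per-map follow-up:

```r
m <- run$maps[[1]]
plot(m, labels = leiden_on_map(m$coords, 20, 0.05, seed = 1))
tree <- build_kdtree(m$coords, max_depth = 3, ids = m$ids)
consensus_at_level(tree, full_seqs <- run$table$fv_heavy[match(m$ids, run$table$id)], level = 3)
```

A thin CLI wraps the same functions:
`Rscript scripts/abmapr-cli.R run --input table.csv --seed 1 --out-dir out`.

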