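# isletnet

Functional connectivity networks from multicellular calcium imaging.

Collectives of coupled cells — pancreatic islets being the canonical
example — coordinate their activity through intercellular communication,
and that coordination can be read out from calcium imaging: each imaged
cell yields a fluorescence time course, and statistically similar time
courses indicate functionally connected cells. `isletnet` implements the
complete analysis chain for researchers working with such recordings:
signal preprocessing, pairwise similarity, network construction and
topology, inter-network comparison, and a ground-truth synthetic islet
simulator for validating every stage.

## The method

Starting from ROI-averaged traces `x_i(t)` sampled at `fs` Hz, with
per-cell positions in µm:

1. **Preprocessing.** Zero-phase band-pass filtering (forward–backward
   Butterworth) separates the fast electrical-bursting component
   (0.05–2.0 Hz) from the slow metabolic component (0.001–0.07 Hz).
   Oscillatory traces are binarized into active/inactive states by a
   per-cell hysteresis rule on a robust percentile amplitude scale; the
   per-cell *relative active time* (duty cycle) is the fraction of active
   frames.
2. **Similarity.** Three pairwise measures: Pearson correlation
   `PC_ij ∈ [−1, 1]` of the (filtered) traces; coactivity
   `CA_ij = Σ_t x_b,i x_b,j / √(Σ_t x_b,i · Σ_t x_b,j) ∈ [0, 1]`, the dot
   product of the unit-normalized binary vectors; and normalized mutual
   information `MI_ij / √(H_i H_j) ∈ [0, 1]` with base-2 entropies
   estimated by frequency counts.
3. **Network construction.** Three routes from a similarity matrix `SC`
   to an undirected graph: a *fixed threshold* (edge iff
   `SC_ij > SC_th`); a *variable threshold* bisected until the average
   node degree hits a target (default `k_avg = 8`); and a *multilayer
   minimum spanning tree* — similarity is converted to the abstract
   distance `D_ij = 2(1 − SC_ij)` and `n` edge-disjoint MSTs are built
   sequentially (default 4 layers, giving `k_avg ≈ 8` with no explicit
   threshold). A *geometric network* connecting physically nearby cells
   serves as the structural reference.
4. **Metrics and comparison.** Average degree `k_avg`, clustering
   `C_avg`, modularity `Q`, global efficiency `E`, relative largest
   component `S_max`, average shortest path `L_avg`, small-world
   coefficient `SW`, hub cells (top 1/6 by degree), physical edge-length
   distributions, and the degree–activity relation. Networks are compared
   by the Jaccard edge-overlap network similarity index
   `NSI = |A ∩ A′| / |A ∪ A′|`, hub overlap, and degree pairing (R²).
5. **Simulation.** `generate_islet()` produces recordings with known
   ground truth: fast bursts propagating as waves from peripheral
   initiator cells, a coherent slow component with cell-intrinsic
   irregularity, heterogeneous duty cycles, indicator-kernel convolution
   and photon noise.

## Worked example

```r
library(isletnet)

islet <- generate_islet(islet_sim_config(seed = 42))
islet
#> <synthetic_islet> 100 cells, 600 s at 5 Hz, 3 initiator(s), 0 async cell(s)

fast <- bandpass_filter(islet$recording, filter_spec("fast"))
S <- pearson_matrix(fast)
net <- fixed_kavg_network(S, target_kavg = 8, coords = islet$recording$coords)
net
#> <functional_network> 100 cells, 403 edges (k_avg = 8.06), method: fixed_kavg
#>   threshold_used = 0.7969

compute_metrics(net, sw_randomizations = 20, seed = 42)
#> <network_metrics> N = 100, edges = 403
#>   k_avg = 8.060  C_avg = 0.492  Q = 0.539  E = 0.338
#>   S_max = 0.950  L_avg = 3.401  SW = 4.182

geo <- reference_geometric_truth(islet, 8)
nsi(net, geo)
#> [1] 0.2810458
```

The fast-component functional network reproduces the hallmarks of islet
connectivity: it is small-world (`SW ≈ 4` against density-matched random
references), modular (`Q ≈ 0.54`), highly clustered (`C_avg ≈ 0.49`),
nearly fully connected (`S_max = 0.95`), and overlaps substantially with
the geometric structural network (`NSI ≈ 0.28`, against ≈ 0.04 expected
between unrelated graphs of this density). With the coactivity measure,
cells with longer duty cycles acquire more connections
(`degree_activity_relation(...)$r ≈ 0.28` in this run), the hub-activity
relation seen in real islets.

The multilayer MST alternative needs no threshold at all:

```r
mst <- multilayer_mst_network(S, n_layers = 4, islet$recording$coords)
mst
#> <functional_network> 100 cells, 396 edges (k_avg = 7.92), method: multilayer_mst
```

`run_pipeline()` executes the whole chain (simulation or CSV input →
bands → similarity → construction → metrics → comparison) from a YAML
configuration and writes CSV/JSON outputs with a checksum manifest; a
thin command-line wrapper lives at `inst/cli/islet-pipeline.R`.

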