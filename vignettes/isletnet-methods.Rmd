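---
title: "Functional connectivity from calcium imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity from calcium imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletnet)
```

`isletnet` turns ROI-averaged calcium traces of a coupled cell collective
into functional connectivity networks and quantifies them. This vignette
is the package's own account of the science: the models and their
assumptions, every tunable parameter with its default and rationale,
what the synthetic-data generator does and does not emulate, and the
design choices made where the methodology was genuinely open.

## Signal model and preprocessing

A recording is a frames × cells matrix of fluorescence intensities with
sampling frequency `fs` (Hz) and per-cell planar coordinates (µm). Islet
calcium dynamics superimpose two oscillatory regimes: a *fast* component
(electrical bursting, roughly 1–5 min⁻¹) that propagates as
intercellular waves, and a *slow* component (metabolic oscillations,
roughly 0.1–0.2 min⁻¹) that is coherent across the tissue.

**Band separation.** `bandpass_filter()` applies a second-order
Butterworth band-pass forward and backward — effective fourth order and
exactly zero phase, so filtering never shifts event times, which matters
because all similarity measures are instantaneous (zero-lag). Named
bands: fast 0.05–2.0 Hz, slow 0.001–0.07 Hz, and a broad "oscillatory"
band 0.005–0.25 Hz suited to isolated-islet recordings. The filter order
is configurable in principle via repeated application; second order
forward–backward is the default because it is stable down to the
extreme cutoff-to-`fs` ratios the slow band requires. Each trace is
mean-subtracted and mirror-padded (odd extension, three settling lengths
of the low cutoff) before filtering to suppress start-up transients;
without padding the filter's initial condition would corrupt a window
comparable to `1/low_cut` at both ends.

**Smoothing.** `smooth_traces()` is a centered moving average with an
odd window; at the edges the window shrinks symmetrically rather than
padding, so no fabricated values enter the trace. The window length is a
free parameter (practitioners choose it relative to `fs`); window 1 is
the exact identity, which the tests pin down bit-exactly.

**Binarization.** The active/inactive state sequence drives the
coactivity and mutual-information measures and the relative active
time. The rule in `binarize()` is hysteresis on a robust per-cell
amplitude scale: baseline = 10th percentile, peak = 95th percentile, a
cell turns active when its signal rises above
`baseline + on_frac · (peak − baseline)` and stays active until it falls
below `baseline + off_frac · (peak − baseline)`. Defaults
`on_frac = 0.5`, `off_frac = 0.3`: the gap between the two thresholds is
what gives noise immunity, and percentiles (rather than min/max) make
the scale robust to outliers. Events shorter than `min_duration`
(default two frames) are discarded as noise crossings. Cells whose
amplitude does not exceed `noise_floor` (default 4) times a robust
frame-to-frame noise estimate — the median absolute first difference
scaled to a Gaussian SD — are declared non-oscillating and set
all-inactive: for pure Gaussian noise the 10th-to-95th percentile range
is about 2.9 SD, safely below the floor, while any genuine oscillation
clears it easily. Manual exclusion of artifact-laden traces is replaced
by an optional automated screen (`snr_screen()`, off by default) using
the same amplitude-to-noise ratio.

Percentile scaling is computed per analyzed interval (not globally):
multi-phase protocols change amplitudes between intervals, and a scale
estimated on one interval would misclassify the other.

## Similarity measures

Three measures, chosen to span linear, overlap-based and
information-theoretic notions of synchrony:

* **Pearson correlation** on (filtered) traces, in [−1, 1].
* **Coactivity**: the dot product of the two binary state vectors
  normalized by `√(Σx_b,i · Σx_b,j)` — the cosine of the unit-normalized
  vectors. This normalization is the one under which the stated range
  endpoints hold exactly (1 for identical vectors, 0 for disjoint
  activity). The plain-product denominator, whose upper bound depends on
  the activity level, is available via `literal = TRUE` for comparison.
* **Normalized mutual information**:
  `MI = H_i + H_j − H_ij` with base-2 entropies from frequency counts
  over the four joint states, normalized by the geometric mean
  `√(H_i H_j)`. The geometric mean is used because it alone maps
  identical series to exactly 1; the plain product is again available as
  `literal = TRUE`. Entropy uses probabilities, with the convention
  `0·log 0 = 0`.

Undefined pairs — zero-variance, all-inactive or zero-entropy cells, and
every diagonal entry — carry an `NA` sentinel and are excluded from all
downstream edge logic, so a degenerate cell can never acquire an edge
through a threshold.

## Network construction

* **Fixed threshold**: edge iff `SC_ij > SC_th`, strictly — ties at the
  threshold are excluded, which makes threshold monotonicity an exact
  set-containment property. Negative correlations get no special
  treatment: anticorrelation never creates an edge.
* **Variable threshold to a target `k_avg`** (default 8, the
  connectivity scale of realistic beta cell architectures): bisection on
  the threshold, at most 60 iterations, tolerance 0.1 on `k_avg`; when
  tied similarity values make the tolerance unreachable, the nearest
  achievable `k_avg` is used and the threshold recorded. The recorded
  threshold supports the carry-over analysis for multi-phase protocols
  (`interval_carryover_networks()`): fix the threshold on interval one,
  re-apply it to interval two, so density changes between intervals
  reflect physiology rather than re-normalization.
* **Multilayer MST**: similarity is recast as the abstract distance
  `D = 2(1 − SC)` and `n_layers` (default 4) edge-disjoint minimum
  spanning trees are built sequentially, each Kruskal pass excluding all
  previously chosen edges. One layer contributes `N − 1` edges (average
  degree just under 2), so four layers give `k_avg ≈ 8` with no explicit
  threshold. Kruskal and Prim coincide for distinct weights; Kruskal was
  chosen, with deterministic lexicographic tie-breaking on the index
  pair for degenerate weights. Because every layer spans all cells, the
  method forces at least `n_layers` connections onto every cell —
  including completely asynchronous ones, which a fixed threshold
  correctly leaves isolated. Both behaviors are asserted in the test
  suite; the choice of construction method is therefore substantive, not
  cosmetic. Any strictly decreasing similarity-to-distance transform
  yields identical trees for distinct weights (a tested invariant), so
  the exact algebraic form of `D` is immaterial to the edge set.
* **Geometric reference**: connect cells within a Euclidean distance
  threshold, either given in µm or bisected to a target `k_avg`
  (default 8, matching the functional networks, since the distance
  threshold equivalent to gap-junctional adjacency is not observable).
  Coordinates are treated as planar (the imaging plane) in µm.

## Metrics

`compute_metrics()` reports `k_avg`, triangle-based local clustering
(isolates contribute 0), modularity `Q` of a greedy
modularity-maximization partition (the algorithm is a free choice; the
greedy agglomerative one is deterministic, and the reported `Q` is
exactly the modularity of the returned partition — a tested identity),
global efficiency `E` (mean inverse shortest-path length over ordered
pairs, `1/∞ = 0`), relative largest component `S_max`, and `L_avg` on
the largest component only (disconnected graphs otherwise have no
finite mean path). The small-world coefficient is
`SW = (C_avg/⟨C_rand⟩)/(L_avg/⟨L_rand⟩)` over `sw_randomizations`
(default 20) random reference graphs with matched node and edge counts
— density-matched Erdős–Rényi references by default, with a
degree-sequence-preserving variant behind `random_ref = "degree"`; the
reference ensemble is seeded and never disturbs the caller's RNG.
Graph-theoretical primitives (components, distances, communities) are
delegated to `igraph`; the test suite checks efficiency and path
lengths against an independent Floyd–Warshall oracle over every graph
on six nodes and random graphs up to twelve.

Hub cells are the top 1/6 of cells by degree — exactly `⌈N/6⌉` cells,
ties broken by cell id for determinism. Edge lengths are Euclidean µm;
the normalized variant divides by the mean distance to the 8 nearest
neighbors averaged over cells, an islet-size-free local scale (with
fewer than 9 cells it falls back to all neighbors, with a warning). The
degree–activity relation bins per-islet normalized degrees (k/max k by
default; k/k_avg behind a flag) and, when pooling islets, normalizes
activity by the islet mean so inter-islet heterogeneity cannot mask or
invert the within-islet relation.

## Inter-network comparison

`nsi()` is the Jaccard coefficient of the two edge sets; two empty
networks are defined as identical (NSI 1, with a warning) — a case real
recordings never produce. `hub_overlap()` normalizes by the hub-set size
(equal in both networks by construction) rather than the union, so the
value is the fraction of a network's hubs recovered in the other.
`degree_pairing()` complements the edge-set view with a per-node one:
the R² of the least-squares degree–degree relation.

## The synthetic islet generator

`generate_islet()` emulates the features of islet recordings that the
analysis chain is sensitive to, with full ground truth. Cells are placed
by seeded dart-throwing in a disc (default 100 cells, radius 120 µm,
minimum spacing 15 µm — beta cell scale). Fast activity: bursts every
20 s (3 min⁻¹) with 5% timing jitter; each burst starts at one
wave-initiator cell — initiators (default 3) are drawn from the outer
20% radial band, as waves in islets originate near the periphery, and
rotate across bursts — and reaches each cell after
`distance/wave_speed` (default 50 µm/s), each cell staying active for
its own duty cycle × period. Duty cycles are heterogeneous
(0.30 ± 0.08, truncated), which is what induces the hub–activity
relation downstream. Slow activity: a sinusoid (period 400 s,
0.15 min⁻¹) whose per-cell phase follows a spatially smooth
kernel-filtered Gaussian field (correlation length 100 µm, SD 0.5 rad)
plus small independent jitter, giving long-range but imperfect
coherence, *plus* a cell-intrinsic irregular drift (white noise through
a second-order low-pass matched to the slow timescale, amplitude 0.7 of
the slow amplitude). The drift term is essential realism: metabolic
oscillations vary in waveform from cell to cell, and without that
variability the slow-band similarity would reduce to a pure phase
metric and produce artificially clustered networks. The drift is
spectrally confined below the fast band so it cannot contaminate
fast-component analyses. Traces are
`1 + amp_fast·(events ⊛ exponential kernel) + amp_slow·slow + noise`,
with an indicator decay of 0.5 s (typical of fast synthetic dyes like
Fluo-4) and Gaussian noise SD 0.05. Asynchronous contaminant cells
(emulating, e.g., alpha cells) get events at independent random times
and a random slow phase.

The wave model is geometric — activation delay proportional to distance
— rather than a biophysical coupled-oscillator ODE. It reproduces every
qualitative structure the analyses detect (distance-decaying fast
correlations, local clustering, peripheral initiators, duty-cycle-driven
degree differences) at a fraction of the cost; what it does *not*
emulate is electrophysiological detail (channel dynamics, gap-junction
conductances), 3D geometry, photobleaching, or motion artifacts. Passing
tests on this generator therefore validate the analysis chain's
correctness and its qualitative discrimination (fast vs slow, sync vs
async), not its robustness to every artifact of real microscopy.

All randomness flows from the single `seed`; identical configurations
are bit-identical, a tested contract.

## Numerical choices and degenerate inputs

* Bisection (threshold and geometric): 60 iterations, tolerance 0.1 on
  `k_avg`, deterministic; unreachable targets raise errors naming the
  achievable maximum.
* Kruskal ties: lexicographic on the index pair; residual-graph
  disconnection mid-layer raises an error reporting the completed layer
  count.
* Flat traces binarize to all-inactive with a warning rather than
  erroring, so one dead ROI cannot abort a recording.
* Empty networks get defined metrics (`C_avg = 0`, `E = 0`, `Q` and `SW`
  as `NA` sentinels).
* NMI values are clipped to [0, 1] against floating-point rounding at
  the `1e-12` scale.

## Problem sizes used in validation

The test and acceptance suites run the full chain on islets of 40–100
cells, 300–600 s at 5 Hz, and five independent seeds for the stochastic
contrasts (fast vs slow clustering, modularity, edge length, and
structural overlap, asserted by majority over seeds); exhaustive oracle
comparisons cover all graphs on six nodes and all 2×2 joint
distributions up to length 10. These sizes match a typical single-islet
field of view and keep the whole suite in the minutes range. The
pipeline-closure check (filter → binarize recovering ground-truth
events) uses a homogeneous duty cycle so that the indicator kernel's
fixed onset/offset lag — not duty-dependent event length — is the only
mismatch being measured.

## Known limitations

* Similarity is instantaneous: no lagged cross-correlation or directed
  (transfer-entropy-style) measures.
* All network analysis is on the binarized edge set; edge weights are
  recorded but not used by the metrics.
* Coordinates are 2D; recordings are analyzed one imaging plane at a
  time.
* Group-level hypothesis testing across cohorts is out of scope — the
  package produces the per-islet quantities such tests consume.
* File interchange is CSV/YAML/JSON.
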