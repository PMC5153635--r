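---
title: "Network topology of impaired consciousness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network topology of impaired consciousness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`docnet` implements a resting-state functional-network analysis of disorders
of consciousness (DOC). Subjects fall into three conscious states —
vegetative state / unresponsive wakefulness syndrome (VS/UWS), minimally
conscious state (MCS), and healthy control — and the question is whether and
how the topology of large-scale brain networks, in particular the
fronto-parietal network (FPN) and the default-mode network (DMN), tracks
conscious state.

The pipeline is, in order:

1. **Nodal time series → Fisher-z connectivity.** Per-node BOLD-like series
   are linearly detrended, band-pass filtered to 0.01–0.08 Hz, residualized
   against nuisance channels (global, white-matter and CSF signals, their
   first derivatives, and six motion channels), and correlated pairwise;
   correlations are Fisher z-transformed, `z = atanh(r)`.
2. **Proportional thresholding.** The `|z|` values are sorted from high to
   low and the top fraction retained as weighted edges, over a grid of
   connection densities from 2.5% to 32.5% in steps of 2%. A density is
   *admissible* when fewer than 10% of nodes are unconnected and the
   network's small-worldness exceeds 1.5.
3. **Topology.** Nodal connectivity strength `s_i = Σ_j w_ij`, degree, and
   weighted betweenness are computed at each density and normalized by
   their means over degree-preserving rewired surrogate networks. Network-level
   values are means over each network's nodes. Clustering (γ) and
   characteristic path length (λ) normalized the same way give
   small-worldness σ = γ/λ. Metrics are summarized across the admissible
   densities by the trapezoidal area under the curve (AUC), removing the
   dependence on any single threshold.
4. **Distance profiles.** Connectivity strength of each FPN/DMN node to
   every other node is binned by Euclidean inter-node distance (18 bins of
   10 mm, 0–180 mm; 75 mm is the short/long convention) and compared across
   groups per bin with one-way ANOVA and Tukey post-hoc tests.
5. **Classification.** Per-subject feature vectors concatenate the three
   AUC-summarized normalized nodal metrics of the selected networks. Three
   one-vs-rest linear SVMs are trained; a held-out subject gets the label
   with the maximal decision score (loss-based decoding reduces to argmax
   here). Performance is assessed by leave-one-out cross-validation (LOOCV)
   and its significance by label-permutation testing.
6. **Group statistics.** Two-way fixed-effects ANOVA (state × network) on
   network-level metrics with Tukey post-hoc contrasts; Pearson
   correlations between FPN and DMN metrics across patients with control
   means as baseline (Bonferroni over the three metrics); a nodal
   permutation test on the average one-way-ANOVA F across the three
   metrics, with Benjamini–Hochberg FDR across nodes.

# The synthetic cohort generator

No clinical data ship with the package; every downstream stage is exercised
on a generator that emulates the statistical structure the analysis
assumes. It is a first-class, tested module, not a fixture.

**Spatial layout.** `make_parcellation()` places one Gaussian cluster per
network lobe (default spread 12 mm). The FPN is deliberately built from two
distant lobes ("frontal" and "parietal", ~112 mm apart) so that long-range
(>75 mm) within-FPN node pairs exist; the DMN is a single compact midline
cluster so within-DMN pairs are predominantly short-range (<40 mm). Node
offsets are clamped at 2.5 SD, bounding all pairwise distances below the
180 mm binning range. The default partition reproduces the published
264-region, 10-network sizes (FPN = 25, DMN = 58).

**Signal model.** Each subject's series are drawn from a zero-mean
multivariate Gaussian whose correlation structure is modular: 0.3 within
networks, 0.05 between, unit variances. These levels produce thresholded
graphs with admissible density ranges and small-world organization
comparable to empirical resting-state data at the study's scan length.
White observation noise (SD 0.2) is added, the series are band-limited with
the same zero-phase Chebyshev filter the analysis uses, and shared nuisance
components are injected: a global fluctuation (gain 0.4), white-matter and
CSF signals (0.3, 0.2), and node-specific couplings to six random-walk
motion channels (SD 0.1). The confound matrix carries the realized global
signal (column means) plus the true WM/CSF/motion channels, so confound
regression is a meaningful recovery problem rather than an identity.

**Planted effects.** VS/UWS covariances gain +0.15 correlation units on
long-range within-FPN pairs and lose 0.15 on short-range within-DMN pairs;
MCS gets ±0.08 (multiplier 8/15); controls are untouched by construction.
The monotone ordering VS > MCS > control mirrors the post-hoc ordering the
analysis is meant to detect. The magnitudes are a design choice: clinical reports of this
kind establish effect *directions* and significance, not correlation-unit
effect sizes, so the defaults are calibrated once to be comfortably
detectable at n = 11/7/11 without being trivial. Positive definiteness
after perturbation is enforced by flooring eigenvalues at 1e-6 and
re-symmetrizing — the simplest deterministic repair.

**What the generator does not emulate:** hemodynamic response convolution,
scanner physics, head-motion spikes and their distance-dependent artifacts,
inter-subject anatomical variability, and non-Gaussian or non-stationary
dynamics. Passing tests therefore show that the pipeline recovers the
planted covariance structure under Gaussian assumptions — not that it would
behave identically on clinical fMRI.

# Preprocessing choices

- **Stage order** is fixed as detrend → band-pass → confound regression →
  correlation. Empirical acquisition pipelines detrend and filter at the image
  level and regress confounds at the nodal level; for nodal-series input
  this serialization is the faithful order.
- **Filter:** Chebyshev Type I, order 4, 0.5 dB passband ripple, applied
  forward–backward for zero phase. The application is vectorized across
  rows and is exactly equivalent (tested to 1e-10) to `signal::filtfilt`
  per row. At 235 samples the edge transient of a constant input leaves
  ~4% of its amplitude in the interior, which is why tests assert ≥95% DC
  attenuation rather than exact zero.
- **Derivatives:** backward differences with first element 0, added for the
  global/WM/CSF channels; among the differencing schemes in use this is
  the common choice.
- **Joint OLS:** motion and signal confounds are regressed in a single
  multiple regression. Sequential partial regressions, the other convention in
  use, differ only in the non-orthogonal overlap; joint OLS is
  order-invariant and idempotent (tested).
- **Fisher-z clamp** at |r| = 1 − 1e-15 keeps duplicated rows finite
  (z ≈ 18) rather than infinite.

# Thresholding and admissibility

Edge counts are `round(density · K(K−1)/2)` with half away from zero
(2.5% of a 264-node graph → 868 edges). Ties in |z| at the cut break by
ascending (i, j) lexicographic order; because the sort order is shared by
all densities, edge sets are nested along the grid (a tested invariant).

Admissibility is evaluated per subject; the pipeline's shared range is the
intersection across subjects. Two exact shortcuts keep the null-model cost
proportional to the useful range:

- **Contiguous truncation.** σ decreases monotonically with density on
  correlation-derived graphs (adding weaker edges dilutes clustering faster
  than it shortens paths), so once σ fails on a well-connected graph, higher
  densities are marked inadmissible without evaluating their ensembles.
  Failures on fragmented very-sparse graphs (≥10% unconnected) do not
  trigger truncation, since σ estimates are not yet in the monotone regime
  there.
- **Intersection-aware capping.** Later subjects skip densities an earlier
  subject has already excluded from the running intersection; those
  densities cannot re-enter the shared range, and nothing downstream reads
  per-subject results outside it.

Both shortcuts change runtime, not results, over the shared admissible
range.

# Topological metrics

Path-based metrics use edge length `1/weight`, the standard convention for
correlation-weighted graphs. Betweenness is normalized by `(K−1)(K−2)/2`.
Characteristic path length is the mean over *finite* shortest-path lengths;
disconnected pairs are excluded (the <10% unconnected criterion makes
disconnection possible, and harmonic-mean efficiency would be a different
metric). Clustering is the geometric-mean (Onnela) triangle form with
weights scaled by the maximum edge weight, zero for nodes of degree < 2,
averaged over all nodes.

Null networks apply Maslov–Sneppen double-edge swaps to the binary topology
(10 attempts per edge — the standard mixing heuristic) and then reassign
the original weight multiset to the rewired edges in random order. Degree
sequence, edge count and weight multiset are preserved exactly; a
consequence worth knowing is that *normalized nodal degree is identically
1*, so degree contributes no variance to the classifier features after
standardization (constant columns are zeroed). Normalization divides by the
null mean with the conventions 0/0 → 1 and x/0 → NA; flagged NAs are
excluded from AUC summaries.

The metric core is implemented in C++ (CSR adjacency, Brandes' algorithm
with a lazy-deletion heap, workspace reuse) because normalization evaluates
these metrics on thousands of rewired graphs per cohort. Correctness is
pinned by two independent oracles: igraph on mid-size graphs (agreement to
machine precision) and exhaustive Floyd–Warshall/path-count enumeration on
all graphs with K ≤ 7 (1000 random instances, including tie-heavy integer
weights).

# Distance profiles

Bins are half-open `[low, high)` with the last bin closed at 180 mm, so a
pair at exactly 75 mm falls in [70, 80). Profiles count ordered pairs
(i in network, j any other node); pairs whose edge did not survive
thresholding contribute weight 0, which preserves the conservation
identity (count-weighted grand mean over bins = overall mean edge weight
from the network). Per-subject bin means are computed at each admissible
density and AUC-summarized before the per-bin ANOVA, matching the AUC
convention of the topological metrics; empty bins are flagged missing, not
zero-filled, and skipped with a warning in the ANOVA.

# Classification

Features are ordered (network, node id, metric: strength, betweenness,
degree); at the study sizes FPN+DMN gives 3 × (25 + 58) = 249 features.
The SVM cost is C = 1 and features are z-scored with training-fold
statistics (the test subject is transformed with those same statistics);
these are fixed conventions, not tuned values — nested hyperparameter
search is out of scope. Decoding takes the maximal
decision score with ties to the lowest class index. The permutation test
permutes all labels once per iteration and re-runs the full LOOCV — the
conservative reading of "randomly assigning label orders" — and the p-value
is the literal proportion of null accuracies ≥ the actual one (no +1
correction, minimum reportable p = 0). Sensitivity is the proportion of the
more-impaired class correctly classified (VS/UWS before MCS before
control).

For the nodal weight map, "summing the feature weights … taking the
absolute value" admits two readings; both are implemented.
`sum_then_abs` (default): |Σ of the nine signed weights per node|;
`abs_then_sum`: Σ|w|. The worked example (1, −2, 0.5) gives 0.5 under the
default and 3.5 under the alternative.

# Group statistics

The two-way ANOVA is a fully crossed fixed-effects fit (state × network,
with interaction); with 29 subjects and 10 networks the error df are
290 − 30 = 260, which is the only design consistent with the reported F
subscripts — a repeated-measures model with subject effects would give
different denominators and is deliberately not used. Effects whose sum of
squares is numerically zero report F = 0 rather than the 0/0 artifact.
FDR is Benjamini–Hochberg; Bonferroni for the network-pair correlations
uses m = 3 (the three metrics). The nodal permutation test re-samples
subjects into three groups of the original sizes, averages the one-way F
over the three metrics per node, and takes p as the null exceedance
proportion (resolution 1/n_perm).

# Numerical and reproducibility choices

- Shortest-path tie detection uses a relative tolerance of 1e-10; edge
  lengths (≥ 1/18 after the Fisher-z clamp) are orders of magnitude above
  it.
- Eigenvalue floor for covariance repair: 1e-6.
- All numeric files serialize at 17 significant digits, so write/read
  round-trips reproduce doubles exactly (tested with `identical()`).
- Every source of randomness flows from one integer master seed; stage and
  subject streams split by FNV-1a hashing of labelled paths
  (`derive_seed(seed, "subject", i)`), keeping derived seeds below 2^31.
  The C++ rewiring uses a splitmix64 stream seeded from R's RNG, so
  `set.seed()` governs it too. Identical configuration + seed gives
  byte-identical reports (tested).

# Problem sizes used by the test suite

The replicated-cohort checks run 20 cohorts at the study conditions (29
subjects, 264 nodes, T = 235) with 20 rewired nulls per density — a
resolution at which null means are stable — and no permutation testing
(the quantities checked are Tukey contrasts, correlations and LOOCV
accuracies). Classifier calibration uses 100 label-exchangeable runs of a
12-subject, 6-feature cohort with 49 permutations each (p resolution
~0.02, which resolves the p < 0.05 event being counted). The acceptance
script runs one full cohort with 20 nulls, 200 classification permutations
and 2000 nodal permutations. These sizes are the package's chosen
trade-off between statistical resolution and a single-CPU runtime.

# Known limitations

- The generator's Gaussianity and single-lobe network geometry are
  idealizations; distance-profile power depends on that geometry.
- Normalized degree is uninformative under exact degree-preserving nulls
  (see above); the classifier effectively uses strength and betweenness.
- Characteristic path length ignores disconnected pairs rather than using
  efficiency; at admissible densities fragmentation is bounded by the <10%
  rule.
- The permutation p-value without +1 correction can be exactly 0; with the
  default 1000 permutations this only means p < 0.001.
- Absolute-threshold graphs, signed networks, community detection,
  rich-club and efficiency metrics, nonlinear kernels and BIDS/NIfTI
  ingestion are out of scope.
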