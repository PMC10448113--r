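---
title: "Methods: quantifying functional odor maps with glomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying functional odor maps with glomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomap)
```

`glomap` quantifies odor maps recorded by volumetric calcium imaging in
the larval *Xenopus laevis* olfactory bulb: ROI-level fluorescence
traces are turned into tuning classifications, sparseness and
correlation statistics, spatial chemotopy tests, molecular-similarity
regressions, mitral/tufted cell (MTC) morphometry and multicolor
projection summaries. This vignette describes the models and procedures
the package implements, the tunable parameters and their defaults, the
synthetic-data generators that stand in for recordings, and the design
choices made where the methodology was genuinely open.

## The acquisition model

All analysis windows derive from an `acq_protocol`: stimuli applied for
5 s at 1 min inter-stimulus onsets, a 15 s lead-in recording, frames at
0.25–2 Hz (default 1 Hz). Each stimulus sequence ("repeat") opens with
the all-odorant mixture followed by the eight single amino acids
(M, L, I, H, K, R, F, W — this panel order is fixed throughout for
labels and matrices). Three windows matter downstream, all anchored on
stimulus onset:

* response window: 15 s from application start (peak amplitudes, SBR
  signal);
* non-stimulus intervals: 15 s starting 25 s after each onset (baseline
  SD, SBR background);
* difference-map windows: peak frame within 8 s post-onset ± 1
  neighbour vs the 5 pre-stimulus frames.

## Trace processing

**Baseline.** Slow drift is removed by asymmetric least squares: the
baseline $z$ minimizes $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i
(\Delta^2 z_i)^2$ with $w_i = p$ above and $1-p$ below the baseline,
iteratively reweighted. Defaults $\lambda = 10^4$ frames² and
$p = 0.01$ are the standard regime for slow drift under sparse positive
transients; both are exposed everywhere. Because the second-difference
penalty leaves affine trends unpenalized, the stiff limit is a straight
line, not a constant — the test suite asserts exactly that.

**ΔF/F and normalization.** $\mathrm{dF/F} = (F - z)/z$; traces are
normalized to their maximum response amplitude (range 0–1). Two
normalizations coexist deliberately: tuning-threshold classification
uses the whole-series maximum (mixture responses included), while
amplitude-vector analyses (correlation, clustering, sparseness,
odor-space coordinates) renormalize to the maximum across the eight
single amino acids via `panel_amplitude_vector()`. Each matches the
convention of the analysis it feeds.

**Peak referencing.** The asymmetric weighting places the ALS baseline
near the lower envelope of the noise, so corrected traces carry a
positive offset of roughly $2\sigma$. Response peak amplitudes are
therefore measured relative to the mean ΔF/F of the non-stimulus
intervals. Without this re-zeroing, threshold classification at
2–3 × SD breaks down at realistic noise levels; with it, planted
dominant tuning is recovered for ≥ 95 % of synthetic ROIs at SNR 10.

**Exclusion rules.** ROIs are dropped when the footprint is under
25 µm² (minimum observed glomerular diameters), when no stimulus peak
exceeds 3 × the non-stimulus SD, or when fewer than two supra-threshold
responses exist (mixture plus at least one single stimulus). The
exclusion log names every violated rule per ROI; manual exclusion flags
are applied last and logged separately. Kept-set size is monotone
non-increasing in each threshold.

**SBR.** The signal-to-background ratio uses the discriminability
denominator $\sqrt{\tfrac12(\sigma_s^2 + \sigma_{ns}^2)}$, making the
measure invariant under gain changes. The typeset source formula is
ambiguous about the radical; the non-radical reading is available via
`radical = FALSE`. Population (denominator-$n$) variances keep the
statistic defined for short windows.

## Tuning, sparseness and clustering

Default and dominant odor tuning are the stimulus sets whose peak
amplitudes exceed 2× and 3× the baseline SD; dominant ⊆ default always,
and labels are canonical panel-order strings ("HFW"). Lifetime
sparseness follows
$S = \bigl[1 - (\sum r_n/N)^2 / (\sum r_n^2/N)\bigr] / (1 - 1/N)$,
0 for uniform and 1 for one-hot responses, invariant under positive
rescaling.

Stimulus clustering is agglomerative average linkage on correlation
distance $d = 1 - r$ over pooled amplitude vectors; pairwise cluster
distances are cophenetic merge heights normalized by the dendrogram's
maximum height (the divisor is a package choice — the source only
states a 0–1 range). The implementation is validated against a
from-definition enumeration oracle.

## Molecular similarity

The eight panel amino acids ship as in-package heavy-atom connection
tables (neutral forms, Kekulé bond orders, PDB atom naming). Two
Tanimoto scores are computed from first principles:

* **MCS**: exhaustive branch-and-bound search for the largest connected
  common *induced* subgraph under element-preserving isomorphism, bond
  orders ignored; score $= |MCS| / (|A| + |B| - |MCS|)$ (atom-counted).
  The induced requirement matters: relaxing it lets a spanning tree of
  the phenylalanine ring embed into the indole system and yields 0.80
  for W/F instead of the published 0.69. The search is exact and fails
  loudly when its node budget is exceeded — never an approximation.
* **Atom pairs**: Carhart descriptors (element, heavy-neighbour count,
  π-electron count; shortest-path bond distance) with multiset
  Tanimoto. π electrons are counted as $\sum (\text{order} - 1)$ over
  each atom's bonds; for this panel the count is independent of the
  Kekulé choice. The typing scheme is isolated in
  `carhart_atom_types()` because atom-pair scores are
  convention-sensitive; the test suite cross-checks the scores against
  ChemmineR's independent implementation.

**Reference-number transposition.** The published accession list
assigns 6306 to "L" and 6106 to "I", transposed relative to the
standard database (6306 is L-isoleucine). Under molecule identity the
M/L atom-pair score is 0.29; under the printed accessions ("as
printed", i.e. the structure the published analysis actually used) it
is 0.31, matching the published value. `aa_molecules()` exposes both
assignments (identity is the default) and `ap_reference_report()`
prints the divergence rather than hiding it. MCS scores are identical
under either assignment.

## Chemotopy statistics

Positions are normalized to the glomerular-cluster boundary box
(affine map to $[0,1]^3$ along the medio-lateral, caudo-rostral and
ventro-dorsal axes). Species territories are member centroids with
per-axis SD (1-SD ellipsoids are descriptive exports only). Two
hypothesis tests probe chemotopy:

* inter-centroid distances, partitioned by whether both species labels
  fall within one structural-similarity group (H/F/W, K/R, M/L/I),
  compared by Mann–Whitney U;
* compound-profile centroid deviation: the distance between a compound
  species' centroid (e.g. "HFW") and the unweighted mean of its
  constituent single-species centroids, similar-compound cohort vs all
  remaining compounds.

Distances default to normalized space; a µm-space flag exists for the
trace-correlation regression where the convention is ambiguous.

**Calibration of the tests.** Pairwise centroid distances share
endpoints, so rank tests on them are not strictly independent samples;
the inflation grows with the number of species entering the pair set.
The package's null calibration therefore evaluates each test on the
species set it is designed for: the inter-centroid comparison on the
eight single-letter species and the deviation test on singles plus
twelve compound species (six within-group, six cross-group), all with
equal member counts so centroids are exchangeable under the null. At
these designs the measured type-I error over 500 uniform-layout
replicates is ≈ 0.03 and 0.04 at α = 0.05. Mann–Whitney cohorts of
three (as with only three compound species per cohort) cannot reject at
α = 0.05 at all — a floor worth knowing when applying the deviation
test to sparse real data.

**The planted alternative.** `chemotopic_layout()` anchors the three
similarity groups at well-separated locations (≈ 0.6 apart), offsets
single species 0.12 from their group anchor, scatters members with
SD 0.06, and places within-group compounds at their constituents' mean.
A compound spanning groups has no central home under chemotopy — its
constituents are far apart — so it is placed inside its first
constituent's territory. Under this layout both tests reach power 1.0
at the calibration sizes; the planted geometry is a strong chemotopic
map, so passing says the tests detect clear chemotopy, not that they
would detect a weak one.

## Morphometry

Reconstructions are rooted trees (SWC; soma = root). Critical points
are end points (no children) and branch points (≥ 2 children), soma
excluded even when it carries several stems. Tufts are DBSCAN clusters
of critical points (Euclidean metric, eps = 15 µm, minPts = 5,
canonical border-point assignment with scan order fixed by node index
for determinism); non-clustered end points are blunt endings. The
implementation is checked against a density-reachability oracle and
recovers planted tuft counts exactly on 200 random trees.

Tuft volume is the 3D convex hull of the cluster's critical points,
computed by exact supporting-plane enumeration (every point triple
whose plane bounds the set contributes a facet; coplanar facet points
are merged via the planar hull; volumes assemble from tetrahedra to an
interior point). The cubic enumeration is exact and fast at tuft sizes
(tens of points); cube and tetrahedron fixtures reproduce closed forms
to 1e-9. Degenerate (coplanar/collinear) clusters get volume 0 with a
flag, not an error.

Soma–tuft distance is measured along the branches to the cluster member
with the smallest path distance (projecting the off-tree cluster center
onto the tree is ill-defined); inter-tuft distances are Euclidean
between cluster centers. The nine PCA features are: tuft count, primary
dendritic stems, mean tuft volume, mean branch points per tuft,
secondary dendrites, primary basal neurites, secondary basal neurites,
mean soma–tuft path distance, mean inter-tuft distance. The last two
complete a seven-item published list with quantities the same methods
compute; that completion is an assumption of this package. Primary
stems are root children whose subtree contains a tuft member; root
children without tufts are primary basal neurites; their children are
the secondary counts. Features are standardized (zero mean, unit
variance) before PCA; constant features are dropped with a log entry.

## Projection colors

Voxels of 3-channel volumes are classified to a primary color iff that
channel is at least 2:1 against *both* others (ties at exactly 2:1
count; the rule is provably exclusive for ratios ≥ 1) and above an
intensity floor. The floor defaults to 0 and exists because the source
analysis thresholded binary stacks manually; synthetic tests set it
just above the noise. Per category and region (GL/MCL masks are inputs;
the generator emits them), coordinate quartiles and centroids are
summarized, and same-color GL–MCL centroid offsets are compared with
cross-color offsets by Mann–Whitney U.

## Statistics module

Shapiro–Wilk for normality, Kruskal–Wallis for > 2 groups, Dunn
post-hoc z tests on pooled mean ranks with tie correction and
Bonferroni adjustment (adjusted p monotone in raw p), Mann–Whitney U
(exact for both n ≤ 8 without ties, normal approximation with tie and
continuity correction otherwise), and the OLS slope t test (an exact
linear relation is reported as p = 0 rather than NaN). Measured null
type-I error of all three comparison tests lies within [0.025, 0.10]
at α = 0.05 over 1000 replicates. Significance markers follow the
figure convention (*** ≤ 0.001, * ≤ 0.05).

## The synthetic-data generators

The generators define the study conditions for every test:

* **Traces**: baseline ≈ 100 a.u. with a low-order polynomial drift
  (±5 % by default), stimulus-locked transients with instantaneous rise
  and exponential decay (τ = 4 s, the order of GCaMP6s kinetics; the
  source states no kernel), onsets snapped to the frame grid so planted
  peaks are realized exactly, and Gaussian noise with
  SD = peak amplitude / SNR. Planted member amplitudes are uniform in
  [0.6, 1]; the mixture evokes the maximum member response so the
  two-response filter rule is exercisable. No quantitative noise/drift
  magnitudes are published; these defaults were chosen once for test
  coverage, not realism.
* **Species**: labels drawn from a frequency table whose default ranks
  single-letter species above within-group compounds, loosely following
  the observed ranking (W, R, KR, M frequent).
* **Trees**: tufts are star-burst arbors whose every node is an end or
  branch point, with spread < 7.5 µm and center separations > 42 µm, so
  the DBSCAN rule recovers planted counts exactly; basal neurites are
  unbranched chains ending in blunt points.
* **Volumes**: Gaussian blobs per channel with 10 % bleed-through on a
  zero background, region masks split along z.

What the generators do *not* emulate: movies (no motion, no source
demixing — the pipeline starts at ROI traces), biophysical calcium
dynamics, correlated or multiplicative noise, z-drift, overlapping
ROIs, and realistic reconstruction noise in trees. Passing tests
demonstrate correctness of the quantification chain under these
idealized conditions, not robustness to raw-data pathologies upstream
of ROI extraction.

## Problem sizes and determinism

The shipped test suite runs the quantification at the following sizes,
chosen so the full suite completes in about a minute on one core:
500 ROIs at SNR 10 for tuning recovery; 500 uniform-layout and 200
chemotopic replicates for the spatial tests; 200 random trees for tuft
recovery; 1000 replicates for the statistical null calibration. All
generators are seed-deterministic: identical seeds give bit-identical
datasets, SWC files and volumes, and `run_pipeline()` derives per-stage
streams from a single root seed.

## Known limitations

* The atom-pair score is convention-sensitive; agreement with other
  software depends on identical atom typing (see
  `ap_reference_report()`).
* The MCS search is exact but exponential in the worst case; it is
  sized for molecules of ~15 heavy atoms and will refuse, not
  approximate, beyond its budget.
* The chemotopy rank tests treat pairwise distances as samples; with
  many species the shared-endpoint dependence inflates type-I error, so
  conclusions on large species sets deserve a permutation check.
* Convex-hull enumeration is cubic in point count — appropriate for
  tuft clusters, not for thousands of points.
* `intensity_difference_map()` picks the peak frame from the global
  mean of the post-stimulus window, which suits compact fields of view;
  per-pixel peak picking would inflate noise.
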