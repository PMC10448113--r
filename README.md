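# glomap

Quantification of functional odor maps in the larval *Xenopus laevis*
olfactory bulb.

Amino acids evoke robust, differential calcium responses in the lateral
glomerular cluster of the larval *Xenopus* olfactory bulb. Recordings at
three network levels — glomerular input (ORN axon terminals), glomerular
output (mitral/tufted-cell tufts and juxtaglomerular neurites), and MTC
somata — raise the same questions: how selective is each unit for the
eight-amino-acid stimulus panel (M, L, I, H, K, R, F, W), do similarly
tuned glomeruli form reproducible spatial territories (chemotopy), and
how does response similarity relate to the molecular similarity of the
stimuli? `glomap` implements the full quantification chain for ROI-level
data, for imaging labs working on amphibian or fish olfaction and anyone
re-analyzing comparable stimulus-locked ROI recordings.

## What it computes

Starting from raw per-ROI fluorescence traces and an acquisition
protocol (5 s stimuli, 1 min inter-stimulus intervals, 15 s lead-in):

* **Trace processing** — asymmetric least squares (ALS) baseline
  estimation, ΔF/F conversion, normalization, response peak amplitudes
  in the 15 s post-stimulus window, and the automatic exclusion rules
  (footprint ≥ 25 µm², ≥ 1 peak > 3 × SD of the non-stimulus intervals,
  ≥ 2 supra-threshold responses).
* **Odor tuning** — default/dominant classification at 2×/3× the
  baseline SD; lifetime sparseness
  `S = [1 − (Σrₙ/N)²/(Σrₙ²/N)] / (1 − 1/N)`;
  signal-to-background ratio
  `SBR = (⟨ΔF/F⟩ₛ − ⟨ΔF/F⟩ₙₛ) / √(½(σₛ² + σₙₛ²))`;
  Pearson correlation matrices; average-linkage clustering of stimuli on
  correlation distance with normalized cluster distances; tuning
  broadness, glomerular-species frequency tables, odor-space coordinates.
* **Molecular similarity** — Tanimoto scores between the panel amino
  acids from first principles: exhaustive connected
  maximum-common-substructure search on heavy-atom graphs
  (`|MCS| / (|A| + |B| − |MCS|)`) and Carhart atom-pair descriptor
  multisets, plus the regression of cluster distances on similarity
  scores (OLS slope test).
* **Chemotopy** — normalized species territories (centroid ± SD
  ellipsoid), inter-centroid distances of similar vs dissimilar species,
  compound-profile centroid deviations, distance-vs-trace-correlation
  regression, and distance by shared-tuning category
  (Kruskal–Wallis + Dunn).
* **MTC morphometry** — SWC trees, end/branch points, DBSCAN tuft
  detection (≥ 5 critical points within 15 µm), convex-hull tuft
  volumes, soma–tuft path distances, the nine-feature morphometric
  vector, and standardized PCA across a cell population.
* **Projection colors** — 2:1 dominant-color voxel classification of
  3-channel volumes and GL/MCL layer correspondence statistics.
* **Synthetic data** — generators for every input (stimulus protocols,
  ROI traces with planted tuning, neuron trees with planted tufts,
  3-channel volumes) with exported ground truth, so the entire pipeline
  is testable without recordings.

## Worked example

```r
library(glomap)

protocol <- make_protocol(repeats = 2, seed = 1)
dataset  <- simulate_roi_dataset(200, protocol, snr = 10, seed = 2,
                                 small_area_fraction = 0.05)

profiles <- lapply(dataset$records, function(r) {
  dff <- normalize_trace(correct_baseline(r$raw_trace)$dff)
  extract_response_profile(dff, protocol, roi_id = r$roi_id)
})
flt <- filter_rois(dataset$records, profiles)
cls <- lapply(flt$profiles, classify_tuning)

amp   <- do.call(rbind, lapply(flt$profiles, panel_amplitude_vector))
spars <- apply(amp, 1, lifetime_sparseness)
fit   <- cluster_distance_vs_similarity(
  stimulus_cluster(flt$profiles)$cluster_distance,
  similarity_matrix(aa_molecules(), "mcs"))
```

With these seeds the run prints:

```
kept 185 of 200 ROIs
most frequent dominant species:  W 27, R 26, M 22, KR 15, L 14, HW 11
median lifetime sparseness: 0.437
cluster distance ~ MCS similarity: slope -0.15, R^2 0.01, p 0.565
planted dominant tuning recovered: 0.957
```

15 ROIs fall to the exclusion rules (small footprints and sub-threshold
responders); the species table mirrors the planted frequency spec; the
sparseness median sits mid-range because the planted population mixes
narrowly and broadly tuned species; and at 200 ROIs of a mixed
population the cluster-distance regression on structural similarity is
flat, as expected when tuning is planted independently of chemistry. The
last line compares each ROI's dominant label against the generator's
ground truth: 95.7% of ROIs are recovered exactly at SNR 10.

`run_pipeline(pipeline_config(seed = 1))` chains all stages (simulate →
process → tuning → chemsim → spatial → morpho → color) and can write a
CSV/JSON report bundle.

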