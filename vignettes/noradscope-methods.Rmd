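---
title: "Methods: quantification pipelines and their synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification pipelines and their synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noradscope)
```

noradscope implements the quantification stages of a locus coeruleus (LC)
axon-degeneration study in the olfactory bulb (OB): odour-evoked
noradrenaline-sensor imaging, histological fibre densities, 3-D engulfment
volumetry, odour-investigation behaviour, and a phagocytosis assay. None of
these stages requires raw microscopy or video data to be validated: each is
paired with a seed-deterministic generator that plants a known ground truth,
and the package's tests assert that the pipelines recover it.

## Odour-evoked sensor movies (dF/F pipeline)

A recording is a 4-D array `(t, z, y, x)` of raw fluorescence from a
genetically encoded noradrenaline sensor, acquired as ~3-minute volumetric
time series at 1.13 Hz with a 10-s odour puff after one minute of baseline.
The analysis chain is:

1. **z-projection** — each time point's stack is collapsed by summation over
   all slices (`project_z()`).
2. **rigid motion correction** (optional) — one integer `(dy, dx)` per frame
   by FFT cross-correlation against a reference, clamped to `max_shift` and
   undone with edge padding (`rigid_correct()`). The reference is the
   temporal mean by default; a first-frame reference is available because a
   displacement shared by almost all frames is indistinguishable from a
   displaced mean and would otherwise be absorbed into the reference itself.
   Non-rigid registration is deliberately out of scope.
3. **dF/F** — per pixel, `(F - F0)/F0` with `F0` the mean over baseline
   frames 20–67; the air puff arrives at frame 68 (`compute_dff()`). Frame
   indices are 1-based and inclusive throughout, so the published window
   numbers can be used verbatim. The first 20 frames are flagged invalid but
   kept in the array, preserving frame numbering; frame 20 itself is valid
   and part of the baseline as printed.
4. **ROI tiling** — the field of view is partitioned into a 6×6 grid of 36
   subtile ROIs (`tile_grid()`); uneven axes give their remainder pixels to
   the first tiles. ROI traces are tile means of pixel dF/F
   (`roi_traces()`).
5. **response statistic and class** — the mean dF/F over frames 89–91
   (`window_response()`), classified as increase/decrease/none against a
   dead band of `k = 2` baseline standard deviations of the ROI trace
   (`classify_response()`).
6. **summaries** — pooled class fractions (`response_fractions()`) and, per
   animal, the grand average of the 3 brightest-at-baseline ROIs of each FOV,
   averaged again across FOVs (`grand_average()`).

Three decisions here were genuinely open and are worth making explicit:

* **Per-pixel vs whole-frame normalisation.** "Frame brightness normalised to
  the baseline" admits both readings. The default is per-pixel F0, which is
  what a spatial response heat map needs; `normalization = "frame_mean"`
  provides the whole-frame scalar alternative. The two agree exactly for
  spatially uniform illumination and differ only through spatial baseline
  texture.
* **The classification dead band.** A pure sign rule would force
  increase + decrease = 100% of ROIs, which cannot reproduce class fractions
  like 75%/5%. The package therefore uses a configurable `k`·sd dead band
  with `k = 2` as default. With the synthetic cohort's planted amplitudes at
  8× the pixel noise, classification is insensitive to `k` over a wide range.
* **Degenerate pixels.** Pixels whose baseline mean falls at or below 1e-6 of
  the movie's global mean (dead or vessel-dark pixels) would blow up the
  ratio; they are flagged and excluded from tile means by default, or can be
  made a hard error. Brightest-ROI ties are broken by ascending ROI index so
  grand averages are deterministic.

### What the movie generator emulates

`gen_twop_cohort()` plants, per ROI of the same 6×6 geometry, a class drawn
with probabilities `p_inc`/`p_dec` and a plateau response kernel starting at
the stimulus frame: linear rise over 10 frames, hold at the planted
amplitude through the response window, linear decay. The baseline is a
strictly positive smooth texture with dark vessel disks, modulated by a
Gaussian depth profile across slices; pixel noise is multiplicative, so
amplitudes are expressed directly in dF/F units. The control-like preset
`wt_fig2` uses 3 animals × 3 FOVs, 203 frames, stimulus frame 68,
`p_inc = 0.75`, `p_dec = 0.05`, amplitudes ±0.04 dF/F and pixel noise sd
0.005. Movies are 120×120 px with 8 z-slices — deliberately smaller than a
real acquisition (~545 px, 30 slices) so that a full cohort generates in
seconds; the tiling is size-agnostic, so nothing in the analysis depends on
this choice. Amplitudes are chosen to be comfortably classifiable; they are
a test harness, not a claim about real response sizes. The generator does
not model optics (PSF, bleaching) or non-rigid tissue motion, so passing
recovery tests demonstrates correctness of the quantification arithmetic,
not robustness to real-world imaging artefacts.

## Fibre densities and relative loss

Histological NET/Iba1/plaque staining is quantified as an area fraction:
threshold, then percentage of foreground pixels (`binarize()`,
`area_fraction()`), optionally within named region masks such as OB layers
(`layer_density()`), averaged over ~4 sections per animal
(`animal_summary()`), and contrasted between groups as
relative density = 100 × mean(case)/mean(control), loss = 100 − relative
density (`relative_loss()`). Manual brightness/contrast adjustment is not
reproducible, so the default pre-thresholding step is percentile
normalisation (1st–99th) followed by Otsu; a fixed-threshold mode exists for
audits, and area fractions under a fixed threshold are invariant to any
monotone intensity rescaling with a correspondingly transformed threshold.

`gen_fiber_image()` rasterises random-walk polyline fibres of a given width
until a planted area fraction is reached (within ±1.5 percentage points of
rasterisation tolerance) and returns the true mask alongside the noisy
image. With the default contrast (foreground 180, background 40, noise sd
8) Otsu recovers the planted per-slice fraction exactly, so cohort-level
recovery error is governed entirely by the sampling of per-slice true
fractions. The `fiberloss_2m/3m/6m` and `dbh_app` presets draw control
slices from Normal(12%, 1%) and case slices from
Normal(12% × scale, 1%) — scales 0.86/0.73/0.67/0.85 — with 4 (or 3) slices
from each of 5 animals per group; all fraction draws come from one seeded
stream per call, with per-slice substreams used only for fibre layout. At
these group sizes the loss estimate carries a sampling sd of roughly 2.3
percentage points; recovered losses at a given seed scatter accordingly
around the planted 14/27/33/15%.

## 3-D colocalization and engulfment

Surface reconstruction is re-implemented as threshold (global Otsu or
fixed) plus 26-connected components with a physical-unit size filter
(`segment_volume()`); commercial surface parameters (smoothing, background
subtraction) are unreported upstream, so this stand-in is documented rather
than claimed equivalent. Metrics are voxel-count volumes: pairwise
colocalised volume and % of one marker inside another (`coloc_volume()`),
engulfed axon volume as the triple intersection NET ∧ CD68 ∧ Iba1
(`engulfed_volume()`), and microglia–axon contact as the shell of an
ellipsoidal physical-radius dilation of Iba1 intersected with NET minus the
direct overlap (`contact_volume()`, reported both as volume and as count of
connected interface components, since "contact points" have no standard
unit). Anisotropic voxels are handled by physical-unit radii rounded per
axis. Normalisation divides a volume by the NET density (NET volume /
imaged volume, `normalize_to_density()`). `gen_coloc_volumes()` builds
sphere-and-tube phantoms with lysosomes placed strictly inside somata, and
stores as ground truth the brute-force voxel recount of every intersection
— the identity the tests assert.

## Behaviour: investigation zones and latencies

Two synchronised cameras film from top (x, y) and side (x, z);
`fuse_views()` scales each view, averages the shared x axis, interpolates
frames missing from one view (flagged), and attaches the odour-tip
coordinate. Zone metrics use the printed definition: a frame is "in the
investigation zone" when the nose-tip Euclidean distance is strictly below
2 cm — a frame at exactly 2 cm is outside. Entries are outside-to-inside
transitions debounced by a 5-frame minimum gap (the upstream definition of
an "entry" is unreported; the gap is configurable and recorded in outputs).
Zone time plus out-of-zone time equals the session duration exactly. The
default phase schedule encodes 2-minute presentations per odour
concentration with 1-minute breaks. Buried-food latencies are consumed as a
table; `latency_contrast()` reports group means ± sem and the percent
change of case over control. `gen_latencies()` draws log-normal latencies
with planted population means (control 40 s, case ×1.60 in the
`buriedfood_3m` preset, cv 0.30, n = 14 vs 18). At those group sizes the
percent-change estimate has a sampling sd near 17 percentage points — a
property of the planted design itself, visible in any single-seed run.

## Phagocytosis assay

The phagocytic index is total integrated cargo fluorescence per image
divided by the adherent cell count (`phagocytic_index()`); zero-cell images
are flagged missing, never treated as zero uptake. Group normalisation
averages technical images within well first, then wells within group, and
expresses each group's 12-h mean as a fold of the control group
(`normalize_to_control()`); folds are invariant to any common intensity
rescaling. `gen_phago_series()` follows a saturating Hill-shaped mean curve
(half-time 6 h), multiplies the case curve by a planted fold (1.33 in
`phago_12h`) at every timepoint, emits 3 technical images per well
(live-cell scans acquire several fields per well), and optionally adds an
actin-blocked group with intensity pinned at ~0.

## Orchestration, determinism and problem sizes

`run_pipeline()` runs simulate→analyse→report over named presets from one
`run_config()` (YAML/JSON loadable), writes tidy CSVs plus a summary JSON
in which every default is echoed, aborts naming the failing stage while
retaining completed outputs, and is bit-reproducible given its seed. All
generators derive per-unit substreams deterministically from one seed, so
identical (parameters, seed) give identical arrays. Default problem sizes —
120×120×8-voxel movies, 192² fibre images, ≤48³ coloc volumes — are chosen
so a full verification run completes in about a minute on a laptop while
keeping every estimator's behaviour visible; all sizes scale up through
preset parameters.

## Limitations

The generators validate quantification arithmetic under idealised imaging:
no point-spread function, photobleaching, non-rigid motion, segmentation
ambiguity, or tracking failures. Agreement between planted and recovered
parameters here therefore does not certify performance on real microscopy
or video data, where thresholding and registration choices dominate.
Transcriptomic analyses, pose-estimation network training, PET
quantification and electrophysiology are out of scope.
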