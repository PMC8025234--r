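---
title: "Methods: models, parameters and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsemetry)
```

synapsemetry implements the quantitative workflow of synaptic cell biology
studies that combine confocal/STED puncta quantification, colocalization and
spatial-segregation statistics, in vivo axonal transport imaging, EM
morphometry and two-electrode voltage-clamp electrophysiology. This vignette
explains the models behind each stage, the parameters that matter, and what
the synthetic-data validation does and does not demonstrate.

## The synthetic-data generators

Every pipeline stage is validated against generators that emit machine-
readable ground truth. They are first-class, tested package code, not test
fixtures.

**Puncta fields.** Spots are rendered as analytic 2D Gaussians — a spot of
amplitude $A$ and width $\sigma$ (px) contributes exactly
$A\,2\pi\sigma^2$ integrated intensity — rather than as disks convolved
with a PSF. The analytic form gives exact integrated-intensity ground
truth, which is what the intensity-conservation checks rely on. Noise is a
two-knob model: Poisson shot noise applied to `signal / poisson_scale` and
rescaled, plus additive Gaussian read noise. The study conditions used in
validation place spots at a minimum separation of $4\sigma$ with peak
signal-to-noise of about 5; real acquisitions do not report their noise
levels, so SNR 5 was chosen once as a level where detection is non-trivial
but reliable, and not revisited.

**Two-channel fields** come in two modes: `shared_fraction` places a set
fraction of spots at identical centroids in both channels (amplitudes drawn
independently), emulating partial colocalization; `center_offset` displaces
every channel-2 partner by an exact physical offset along a set direction,
emulating segregated cargo classes within one aggregate.

**Transport movies** move particles along a 1D path coordinate rendered
into 2D frames — the same reduction a kymograph performs. Positive
velocities increase the path coordinate (anterograde; paths are stored
proximal-end-first). Start positions are drawn so a particle remains on the
path for the whole recording whenever the path is long enough; otherwise it
is truncated at the path end and flagged in the truth table. Pauses are
per-frame Bernoulli events that freeze the path coordinate.

**EM sections** are non-overlapping ellipse profiles with configurable
long-diameter and elongation distributions; defaults (72 nm long diameter,
elongation 1.79) match the vesicle populations these methods are used on.
A separate stereology generator cuts a periodic box of equal spheres at
known volume fraction with random planes, which is the textbook setting for
the Delesse areal-fraction estimator.

**Evoked-current traces** are peak-normalized biexponentials
$A\,[e^{-t/\tau_d} - e^{-t/\tau_r}]/k$ on a constant holding current, with
$k$ chosen so the transient's extremum equals $A$ exactly. Defaults
($\tau_r = 1$ ms, $\tau_d = 5.5$ ms, $A = -75$ nA, 10 kHz sampling) are
typical of evoked junctional currents at the larval neuromuscular junction.

What the generators do **not** emulate: anisotropic/3D PSFs,
photobleaching, focus drift, structured (tissue) background, and particle
crossings in the image plane. Passing tests therefore demonstrate
correctness of the measurement operations under controlled conditions, not
robustness to every artifact of real acquisitions.

## Puncta detection and per-particle statistics

The detection pipeline fixes the classical order of operations: maximum
projection, background subtraction, manual threshold, light Gaussian blur,
maxima-seeded splitting, and re-projection of the binary mask onto the
original image (a per-pixel min) so that **all intensity statistics are
computed on pre-blur intensities** — the blur exists only to stabilize
segmentation.

Key choices:

* *Background subtraction.* The classical rolling-ball is implemented as a
  grayscale opening with a disc (radius 50 px by default, configurable); a
  percentile subtraction is available for flat backgrounds.
* *Thresholding.* The reference workflow uses a manual threshold per
  dataset. Batch runs can fall back to Otsu, which is clearly a departure
  from the manual protocol and is labeled as such in the configuration.
* *Find maxima.* Local maxima are filtered by topographic prominence (the
  "noise tolerance" notion): a peak survives if one must descend at least
  the tolerance below its height before reaching higher ground. The
  implementation is a descending union-find flood; the test suite checks it
  against an independent brute-force level-scan oracle on small images.
  Accepted maxima seed a watershed (seeded region growing) that partitions
  the threshold mask; this replaces the manual pencil-tool splitting of the
  source workflow with a deterministic equivalent.
* *Coordinates* are 0-based with pixel centers at integer positions; areas
  convert by `pixel_size^2`.

Field summaries report particle density (count per reference area) and sum
intensity per area (summed per-particle integrated densities over the
reference area, an estimate of total protein in the imaged tissue), with
optional percent-of-control normalization in which the control group mean
is exactly 100%.

The bouton-cytoplasm measurement blurs a copy of the image (sigma 2.0 px),
thresholds it (default 30) to find active zones, subtracts those regions
from the bouton ROI and averages the original image over the remainder.
The ring-diameter conversion is the closed form $d = 2\sqrt{A/\pi}$.

## Colocalization

`pearson_above_threshold()` computes the Pearson correlation over
qualifying ROI pixels and repeats it after mirroring the second channel
left-right within the ROI bounding box — the flipped image preserves the
channel's own intensity structure while destroying its spatial relation to
the first channel, so `r_flipped` estimates chance colocalization.

The qualifying-pixel rule was a genuinely open design point. We measured
both candidates on independently generated fields: with the OR rule (pixel
used if *either* channel exceeds its threshold) the qualifying set is
dominated by bright-in-one/background-in-the-other pixels, which imposes a
structural anti-correlation of roughly $-0.1$ on channels that are
spatially independent — the null the control exists to calibrate is then
biased. The AND rule keeps the independent-field correlation centered on
zero while preserving $r = 1$ for identical channels and a monotone
response to the generator's shared fraction. AND is therefore the default;
OR remains available via the `qualifying` argument.

Thresholds default to per-channel Otsu inside the ROI but should be set
explicitly where the acquisition's background is known. No Costes
randomization and no Manders coefficients are provided.

## Spatial statistics

Line profiles are sampled at one-pixel steps with bilinear interpolation
and averaged across a configurable perpendicular width. The peak-to-peak
distance takes channel 1's global profile maximum and the nearest local
maximum of channel 2; an all-pairs-nearest mode exists for batch use.
Distances are binned at 0.06 µm up to a 1.2 µm cutoff and reported as
percent per bin (each distribution sums to 100%).

The chance distribution comes from translating the second channel by 80 px.
The shift wraps around (circular) rather than cropping: wrapping preserves
the pixel count and intensity histogram, so data and null distributions are
built from images with identical content. Whether the original protocol
wrapped or cropped is not documented; wrap was chosen and is stated here.

Center-of-mass distances use intensity-weighted centroids (not binary
centroids) over each channel's thresholded ROI, then the Euclidean distance
$d = \sqrt{(x_1-x_2)^2 + (y_1-y_2)^2}$ in physical units.

## Axonal transport

Frames are registered by translation-only phase correlation against the
first frame (integer-pixel shifts, applied with wrap-around). Kymographs
stack one background-subtracted, lightly blurred (sigma 0.5 px) line
profile per frame.

Track detection thresholds the kymograph and finds connected streaks. A
particle moving $v$ µm/s steps $v\,\Delta t/\text{pixel size}$ px between
rows, so streaks of fast particles are not pixel-connected; components are
linked across a horizontal dilation (default bridging 15 px/frame,
configurable) while statistics are computed on the original
above-threshold pixels. Each component is reduced to per-frame
intensity-weighted positions; it is accepted as a track when

* it is unidirectional — at most 10% of frame-to-frame steps larger than a
  quarter pixel oppose the net direction (pauses are not counted), and
* its spatial extent is at least 4 µm **and** its temporal extent at least
  30 s, both bounds inclusive.

Speed is spatial extent over temporal extent; direction follows the slope
sign with anterograde defined as increasing path coordinate. Cotransport
samples the second channel's kymograph in a ±2 px band around the track
and requires the co-channel to exceed its threshold in at least 3 distinct
time rows ("three or four" in the source protocol; the weaker bound is the
default and is configurable).

Validation uses single-particle movies (50 for the speed/direction check,
40 for cotransport). With one particle per movie, a per-movie cotransport
fraction of 0.5 is not meaningful, so the ensemble draws each movie's
cotransport flag Bernoulli(0.5) under the run seed and compares the
recovered fraction with the exact binomial interval. Crossing-particle
linking is out of scope, as kymograph-domain analysis is.

## EM morphometry

Per-region long/short diameters come from the moment ellipse (eigenvalues
of the second central moments, with the 1/12 pixel-footprint correction);
a Feret-caliper alternative is available. Elongation is defined as
long/short ≥ 1. (Published figure labels sometimes print the inverse name
while reporting long/short values; the package standardizes on long/short
for internal consistency.)

Volume fractions use the Delesse principle — the areal fraction of
labeled profiles within a reference region on a random section is an
unbiased estimator of volume fraction — computed from full-area
segmentation rather than point counting, since label images make
exhaustive measurement exact.

For 3D labels, volume is the voxel count times voxel volume. Surface area
is computed by the coarea formula: the binary indicator is mollified with a
Gaussian (sigma 1 voxel) and the gradient magnitude integrated. No
installed mesh/marching-cubes machinery is required, and the estimator is
accurate to about 0.3% on a 30 nm sphere at 1.5 nm voxels (tested, along
with an ellipsoid and the isoperimetric lower bound). Labels touching the
volume border are flagged `clipped`.

T-bar annotations (roof line, pedestal line, area polygon) are converted
to physical units with polyline length and the shoelace formula;
self-intersecting polygons are rejected.

## Electrophysiology

`evoked_metrics()` measures baseline (mean over a pre-stimulus window),
signed amplitude, 10–90% rise time, decay $\tau$ and charge (trapezoidal
integral of the baseline-subtracted current; 1 nA·s = 1000 pC). Inward
currents are negative; amplitude and charge keep their sign, the
paired-pulse ratio is reported on magnitudes.

Numerical choices worth knowing:

* The peak search and the no-response gate run on a 3-sample running mean.
  At 10 kHz the raw per-sample maximum of pure noise exceeds 3 SD with
  near-certainty ($\sqrt{2\ln N}$ growth), so gating on raw samples would
  declare responses in flat traces; the short smoothing makes the 3-SD rule
  usable while biasing a realistic peak by well under 0.1%.
* A 1 ms post-stimulus blanking window (configurable) excludes stimulation
  artifacts from the peak search only.
* The decay fit is a mono-exponential least-squares fit on the falling
  phase between 70% and 10% of the peak deviation (configurable via
  `decay_from`/`decay_to`). Starting at the peak itself contaminates the
  fit with the rising exponential and biases $\tau$ upward by ~10% at
  $\tau_r/\tau_d = 1/5.5$; starting at 70% keeps the bias at or below
  ~1.5% across the tested noise levels while using most of the decay.
* The paired-pulse second amplitude subtracts the first response's fitted
  exponential extrapolated to the second peak time; the alternative
  (subtract the current just before the second stimulus) is available via
  `correction = "pre_pulse"`.

Miniature-event detection and kinetics are out of scope.

## Statistical decision tree

`route_and_test()` reproduces the normality-gated routing used throughout
this literature: each group is tested with the D'Agostino–Pearson omnibus
test (implemented from the skewness and kurtosis transforms; verified
against an independent implementation to 10 decimal places) at $\alpha =
0.05$. Groups too small for the omnibus test are *assumed* normal; the
test requires $n \ge 8$, so the cutoff is `normal_min_n = 8`
(configurable — source documents are inconsistent between "n > 7" and
"n < 7", and the mathematical requirement resolves the ambiguity). Two
all-normal groups route to the unpaired two-tailed t test (classical
equal-variance form); any non-normal group makes the comparison
nonparametric (Mann–Whitney U); more than two groups route to one-way
ANOVA with Tukey's post hoc or Kruskal–Wallis with Dunn's post hoc
(Bonferroni-adjusted), respectively. Stars map p < 0.05/0.01/0.001.

`percent_of_control()` rescales every value by the control-group mean, so
the control group averages exactly 100%.

## Problem sizes and reproducibility

The validation suite and the acceptance script use 512² px fields with 200
spots for detection, 20 replicates per level for the shared-fraction sweep,
30 pairs per offset for center distances, 120 line profiles for the
peak-to-peak distributions, 50 + 40 single-particle movies (61 and 36
frames at 1 s) for transport, 100 random sections for the Delesse check,
and 1000 replicates for the type-I simulation — sizes at which every
stochastic check has comfortable margin against its tolerance while the
whole suite runs in minutes on one CPU.

All generators take explicit integer seeds and produce bit-identical
output for equal seeds; `run_pipeline()` echoes its configuration, stamps
every CSV with the configuration hash, and is byte-reproducible for a
fixed seed. Images are interchanged as 32-bit multi-page TIFF with a JSON
sidecar holding calibration and the integer quantization step, which makes
write/read round trips exact for integer-valued data.

## Known limitations

* Detection is projection-then-2D only; no voxel-level 3D segmentation.
* Kymograph analysis cannot disentangle particles that cross in the image
  plane, and the automated streak detector assumes a dominant particle per
  path at a time.
* The registration is translation-only and integer-pixel, which matches
  the stabilization needs of the data class but not rotational drift.
* The flipped-channel and pixel-shift nulls calibrate *chance* overlap for
  structures of the observed size and density; they do not model spatially
  structured backgrounds shared by both channels, which would inflate both
  data and control values.
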