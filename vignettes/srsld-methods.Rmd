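---
title: "Quantifying neutral lipids from hyperspectral SRS images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neutral lipids from hyperspectral SRS images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsld)
```

# The measurement problem

Stimulated Raman scattering (SRS) microscopy images molecular vibrations
label-free; the stimulated Raman loss signal is linear both in the
concentration of the vibrating species and in the product of pump and
Stokes laser power. In the CH-stretch region the two neutral-lipid
classes stored in lipid droplets (LDs) — triacylglycerol (TAG) and
cholesteryl ester (CE) — have distinct, overlapping spectra: TAG peaks
near 2857 cm^-1 (symmetric CH~2~ stretch of open acyl chains) and CE
near 2875 cm^-1 (CH~2~ stretch within the sterol ring). A single-band
image therefore cannot separate them, but a hyperspectral cube sampled
across the fingerprint (1625–1775 cm^-1) and CH-stretch (2800–3100
cm^-1) windows can, pixel by pixel.

`srsld` implements this decomposition and everything around it: the
spectral axis, reference-spectrum construction, per-pixel non-negative
unmixing, nucleus/cell/droplet segmentation, per-droplet and per-cell
lipid statistics, subcellular-distribution metrics, and clustering of
nuclear-pore coordinates. A synthetic scene generator with known ground
truth makes every stage testable without microscope data.

# Spectral axis and references

The axis is the concatenation of per-region regular grids
(`build_spectral_axis()`). A wavenumber shared by two adjacent regions
(2950 cm^-1 in the default three-region layout) is kept as two distinct
channels, because each is a separately acquired image plane; the default
axis thus has 3 × 51 = 153 channels.

The reference matrix *S* (channels × 4) holds the TAG, CE,
cellular-background and water-background component spectra
(`extract_reference_set()`). TAG and CE references come from manually
selected droplets of cells loaded with only oleic acid or only
cholesterol (typically 5–12 droplets per load); the cellular background
from cytoplasmic regions of lipid-starved cells (4–7 regions); the water
background from cell-free areas (2–4 regions). Deviations from these
counts are reported but not fatal. Each component is the mean spectrum
over its pooled ROI pixels; the cellular background is subtracted from
the TAG and CE columns, capped at 0 so no reference goes negative.
References stay on the raw intensity scale — weights are used as
absolute lipid-amount proxies, so no per-spectrum normalization is
performed anywhere.

# Per-pixel non-negative unmixing

Each raw pixel spectrum *d* is decomposed as the non-negative linear
combination of the four reference spectra: minimize ‖*S w* − *d*‖~2~
subject to *w* ≥ 0 (`nnls_pixel()`, `decompose_cube()`), i.e. the
Frobenius objective ‖*W S*^T^ − *D*‖~F~ over all pixels. Pixel spectra
are **not** background-subtracted first: the cellular-background column
inside the model performs a pixel-wise scaled subtraction implicitly,
and subtracting beforehand would bias droplet pixels whose background
share differs from the image-wide mean.

The solver is a Lawson–Hanson active-set iteration run on the normal
equations (Gram matrix *S*^T^*S* and *S*^T^*d* are computed once per
cube), which terminates finitely and exactly for the 4-component case.
`decompose_cube()` first solves the unconstrained system for all pixels
in one vectorized step and falls back to the active-set loop only where
that solution is infeasible — identical results, since a feasible
unconstrained optimum is the NNLS optimum. The test suite checks the
solver against an independent oracle that enumerates all 16 support
subsets, and against an independent NNLS implementation.

The TAG and CE weight planes are the *SRS lipid intensities*. They are
linear in acquisition settings, so `normalize_weights()` rescales by
(pump×Stokes)~target~ / (pump×Stokes)~measured~ — per acquisition region
when powers differ by region, using the region where each component's
reference peaks — before any cross-acquisition comparison. Whether zoom
changes the per-pixel intensity (and not only the pixel footprint)
depends on the instrument; the zoom correction exponent is therefore
exposed (`zoom_exponent`, default 0 = purely geometric).

# Saturation

Lock-in detector saturation clips spectra into flat, high plateaus and
corrupts the decomposition. `detect_saturation()` flags a pixel when any
sliding window spanning 12 cm^-1 (5 channels at the 3 cm^-1 step) has
sample standard deviation below 50 counts while all its values exceed
3500 counts (≈85% of the 12-bit maximum 4095). Windows never cross
region boundaries — a window across the 1775→2800 cm^-1 gap would not be
a contiguous spectral range. Droplets with ≥20% saturated pixels are
excluded from quantification; saturated pixels are grayed in
false-color renderings, as are pixels outside the segmented cells.

# Segmentation

* **Nuclei** (`segment_nuclei()`): Gaussian blur (σ = 2 px), Otsu
  threshold, hole filling, distance-transform watershed to split
  touching nuclei, minimum area 64 px. This classical route replaces
  the deep-learning nucleus segmentation used in high-content practice;
  the package accepts externally produced nucleus label images wherever
  masks are consumed, so a learned segmentation can be substituted on
  real data.
* **Cells** (`propagate_cells()`): seeded region growing around the
  nuclei over the mean-collapsed SRS image, in the style of
  CellProfiler's IdentifySecondary "Propagation" (EBImage `propagate`);
  the regularization λ (default 0.05) balances Euclidean distance
  against local intensity differences. For screening data,
  `filter_small_cells()` removes cells below an equivalent-circle
  diameter of 20 µm.
* **Droplets** (`detect_droplets_atrous()`): B3-spline à trous wavelet
  decomposition; detail planes 2..levels are thresholded at
  `k_mad` × MAD and ANDed. Two additions make the detector specific to
  compact bright spots: a white top-hat gate (disc diameter 13 px)
  that suppresses step-edge responses at cell borders — a half-plane or
  a large disc is open under the disc brush, so its top-hat is zero,
  while blobs smaller than the brush survive — and a watershed split of
  merged detections on the summed positive wavelet response. Defaults
  are levels = 3 and k_mad = 5: with a 4th level the AND requires
  support at ~16 px scale and misses 2–3 px-radius droplets, and at
  k_mad = 3 faint edge/noise responses survive; the chosen defaults give
  precision and recall ≥ 0.98 on the default synthetic scene at 0–2%
  noise. Note the MAD of a structured detail plane overstates the noise
  scale, so k_mad = 5 is a considerably milder cut than "5 sigma".

The mean-collapsed image used for segmentation and display subtracts the
acquisition-specific cover-glass background — the mean spectrum of the
2000 pixels with the lowest channel-mean (clamped to 10% of the pixels
for small images when left at its default) — capped at 0, then averages
over all channels. The collapse uses all channels, including the
fingerprint region (whether to exclude it is not specified by
convention; including it is the simpler choice and only affects
segmentation contrast, never the decomposition, which always sees raw
spectra).

**NE-LDs** are droplets whose mask overlaps the nuclear mask by at least
one pixel, partial overlap included; a droplet overlapping two nuclei is
NE if it overlaps any. Droplets attach to the cell with majority mask
overlap, or to the nearest cell within 5 px, otherwise they are dropped
with a message.

# Lipid statistics

Per droplet (`droplet_records()`): TAG and CE weight sums over the
droplet pixels, CE fraction CE/(CE+TAG), NE flag, saturated-pixel
fraction, and the equivalent radius √(area/π) · pixel size (the natural
radius definition for a mask of counted pixels). Per cell
(`cell_summaries()`): droplet-pool and whole-cell-pool sums (the
difference is the diffuse membrane pool), NE-droplet fraction, and the
CE-in-NE share. Cells without droplets report missing values for the
ratio metrics and are thereby excluded from their condition means.

`size_ce_histogram()` bins droplets by equivalent radius × CE fraction,
with open underflow/overflow bins so every record is counted.
`anchor_normalize()` makes SRS weight sums comparable with biochemical
(thin-layer chromatography) lipid masses by dividing each table by its
own CE value at a shared anchor condition (conventionally the
cholesterol + oleic-acid double load); the anchor CE is 1 in both tables
by construction, so only the *relative* pattern across the other
conditions carries information. Group comparisons mirror common figure
practice: Welch's t-test for CE fractions and intensities
(`compare_ne_vs_cyto()`), Mann–Whitney U as the option for count-like
variables; when both groups are essentially constant the standard error
is floored at machine epsilon instead of failing.

# Subcellular-distribution metrics

The **nuclear-proximity score** (`nuclear_proximity()`) is the
intensity-weighted mean of d~PM~/(d~N~+d~PM~) over cell pixels, with
d~N~ the Euclidean distance to the nucleus mask and d~PM~ the distance
to the outer contour of the cell mask (cell pixels 4-adjacent to
background, which have d~PM~ = 0). It is 1 for purely nuclear signal, 0
for signal on the cell contour, invariant to intensity scaling, and
includes all cell pixels — nuclear pixels (d~N~ = 0) contribute weight 1
by the formula, so no cytoplasm-only restriction is needed.

The **nuc/cyto translocation ratio** (`nuccyto_translocation()`) is
(nuclear mean − background)/(cytoplasmic mean − background) with the
well-level background the mean intensity outside every cell mask (a
median alternative is exposed for robustness); non-positive
background-subtracted cytoplasm flags the record invalid rather than
returning a misleading ratio. Ratios are reported relative to the mean
ratio of a designated baseline condition. For z-stacks,
`select_focus_slice()` either picks the slice maximizing the
nuclear-stain total (ties to the lowest index) for all channels, or
maximum-intensity-projects. `dendra2_ratio()` supports photoconversion
time series as red nuclear ROI mean over pre-conversion green ROI mean.

# Nuclear-pore clustering

`cluster_pores()` builds a neighborhood graph over pore coordinates
(edges where pairwise distance < threshold) and takes connected
components as clusters. In 3D the threshold is adjusted for nucleus
size as base · (volume/reference volume)^1/3^ — a length scale should
grow with the cube root of a volume; the exponent is configurable since
only "adjusted with the volume" is conventional. In 2D a fixed threshold
is used. The implementation (distance matrix + graph components) is
checked against a brute-force all-pairs union-find oracle.
`detect_pores_2d()` reuses the à trous spot detector on a pore channel
or an externally supplied pixel-classification probability image; two
spots closer than the detector resolution merge into one centroid, a
documented limitation. `pore_density()` is the count per µm².

# The synthetic scene generator

`make_component_spectra()` evaluates a declared Lorentzian peak model on
the axis: TAG anchored at 2857 cm^-1 with a 1745 cm^-1 ester-carbonyl
band, CE at 2875 cm^-1 with a 1670-region band, a broad low cellular
background, and a water background with a broad O–H tail above 3000
cm^-1. Only the two CH-stretch anchors are literature-fixed; the
remaining bands are a plausible model kept in one versioned table so
tests stay stable. The four spectra are linearly independent (condition
number ≈ 6.7 on the default axis, attached as an attribute).

`render_scene()` lays out cells on a grid (default 256 × 256 px, 6
cells), dark elliptical nuclei (cellular-background concentration
reduced to 0.35 inside, since nuclei appear dark in SRS), and hard-disk
droplets of radius 2–5 px that never overlap; NE droplets are centered
on the nucleus boundary so their masks partially overlap the nuclear
mask. Per-droplet CE fractions are drawn from normal distributions —
cytoplasmic mean 0.35, NE mean 0.45 (a +0.1 offset in the direction of
the CE enrichment of NE droplets), sd 0.05, clamped to [0, 1]; amplitudes
are uniform in 800–1600 counts so the 12-bit cube stays clear of
clipping. Options add a diffuse cytoplasmic CE pool (membrane analog)
and a CE-shell/TAG-core radial profile. The cube is the concentration
maps times the spectra, rounded and clipped to 12 bits; the truth bundle
carries the concentration maps, droplet table, masks and a companion
nuclear-stain image. `corrupt_cube()` adds Gaussian noise (σ as a
fraction of the cube maximum) and can scale selected droplets into a
flat plateau just below the detector maximum, reproducing lock-in
saturation so the saturation rule fires by construction.

What the generator does *not* emulate — chirp and spectral-focusing
artifacts, cross-phase modulation, detector nonlinearity, textured
cytoplasm, out-of-focus light, droplets below pixel scale — bounds what
green tests mean: they validate the algorithmic chain (unmixing,
segmentation, statistics) under the stated image model, not instrument
physics on real acquisitions.

# Numerical choices and problem sizes

* NNLS tolerance: gradient cut at 1e-12 × max(|S^T^d|, 1); results match
  the exhaustive oracle to ≤ 1e-9 in residual.
* Quantization: 12-bit rounding limits noise-free per-droplet recovery
  to ~0.1% relative; the float path (no quantization) recovers to 1e-6.
* Ties: focus-slice selection takes the lowest index; cover-glass pixel
  ranking is stable in pixel order.
* Coordinates are pixel-centered, row-major and 0-based in CSV outputs.
* Determinism: every stochastic step is seeded from the run
  configuration; two runs with one seed give byte-identical CSVs.
* Test and example problem sizes are desk scale by design: 256 × 256 ×
  153 cubes (the acceptance scene), a 320 × 320 scene with ~200 droplets
  for the NE-enrichment recovery, ≤ 200 points for pore-cluster oracle
  checks.

# Known limitations

Real reference spectra vary with acyl-chain composition; the package
treats TAG and CE as single components, as does the underlying model.
The classical nucleus segmentation assumes high-contrast stains and will
underperform learned models on crowded fields (external label images are
accepted for that reason). The saturation rule's thresholds (50 counts,
3500 counts, 12 cm^-1) are instrument conventions exposed as arguments,
not universal constants. The à trous detector merges spots closer than
its resolution. File I/O stores 12-bit cubes in 16-bit TIFF pages and
weights as scaled 32-bit floats; both round-trip within their
representable precision.
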