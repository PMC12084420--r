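# srsld — hyperspectral SRS unmixing and lipid-droplet quantification

`srsld` is an R package for quantifying the two neutral-lipid classes of
lipid droplets — triacylglycerol (TAG) and cholesteryl ester (CE) — from
hyperspectral stimulated Raman scattering (SRS) image cubes, for cell
biologists and imaging scientists working on lipid storage and its
subcellular organization.

An SRS cube samples each pixel's Raman spectrum over the fingerprint
(1625–1775 cm⁻¹) and CH-stretch (2800–3100 cm⁻¹) windows at a 3 cm⁻¹
step (153 channels). TAG and CE have overlapping but distinct spectra
(CH₂ symmetric stretch at ≈2857 cm⁻¹ for acyl chains vs ≈2875 cm⁻¹ for
the sterol ring), so each pixel spectrum *d* is decomposed against a
reference matrix *S* (columns: TAG, CE, cellular background, water
background) by non-negative least squares:

    minimize ‖S w − d‖₂   subject to   w ≥ 0

equivalently ‖W Sᵀ − D‖_F over all pixels of the cube. The non-negative
weights *w* are used directly as SRS lipid intensities. Around this core
the package provides:

* reference-spectrum extraction from annotated droplet/cytoplasm/water
  ROIs, with capped background subtraction;
* lock-in saturation detection (flat spectral plateaus: windowed sd < 50
  over 12 cm⁻¹ at values > 3500) and acquisition-settings normalization;
* nucleus, cell and droplet segmentation (Otsu + watershed, seeded
  propagation, B3-spline à trous wavelet spot detection) and
  classification of nuclear-envelope-associated droplets (NE-LDs: any
  overlap with the nuclear mask);
* per-droplet / per-cell statistics — CE fraction CE/(CE+TAG), the
  <20%-saturated-pixels filter, size × composition histograms, anchor
  normalization against thin-layer chromatography tables, NE-vs-cytoplasm
  group tests;
* subcellular-distribution metrics: the intensity-weighted
  nuclear-proximity score Σₖ (iₖ/I) · d_PM,k/(d_N,k + d_PM,k),
  background-subtracted nuclear/cytoplasmic translocation ratios,
  focus-slice selection, photoconversion ratios;
* neighborhood-graph clustering of nuclear-pore coordinates with
  nucleus-size-adjusted thresholds;
* a synthetic hyperspectral scene generator with full ground truth, so
  the entire pipeline is testable without microscope data.

See `vignettes/srsld-methods.Rmd` for the methods and design rationale.

## Worked example

Generate a synthetic scene, unmix it, segment it, and compare NE with
cytoplasmic droplets:

```r
library(srsld)

axis    <- build_spectral_axis(srs_default_regions())   # 153 channels
spectra <- make_component_spectra(axis)
scene   <- render_scene(scene_layout(), spectra, seed = 7)

wi  <- decompose_cube(scene$cube, scene$refs)           # per-pixel NNLS
col <- mean_collapse(scene$cube, cover_glass_background(scene$cube))
nuc <- segment_nuclei(scene$truth$nuclear_stain)
masks <- segmentation_masks(nuc,
                            propagate_cells(nuc, col),
                            detect_droplets_atrous(col),
                            pixel_size_um = 0.25)

rec <- droplet_records(wi, masks)
head(rec[, c("droplet_id", "cell_id", "is_ne", "pixel_count",
             "tag_sum", "ce_sum", "ce_fraction")], 4)
#>   droplet_id cell_id is_ne pixel_count  tag_sum   ce_sum ce_fraction
#> 1          1       3 FALSE          29 30026.01 14562.36   0.3265954
#> 2          2       5 FALSE          29 28896.45 14578.51   0.3353312
#> 3          3       1  TRUE          29 24656.29 21667.67   0.4677422
#> 4          4       1 FALSE          49 46610.36 30459.60   0.3952201

cmp <- compare_ne_vs_cyto(rec)
sprintf("NE mean CE fraction %.3f vs cytoplasmic %.3f (Welch p = %.2g)",
        cmp$mean_ne, cmp$mean_cyto, cmp$p_value)
#> "NE mean CE fraction 0.439 vs cytoplasmic 0.363 (Welch p = 1.2e-05)"
```

`tag_sum`/`ce_sum` are the droplet's SRS lipid intensities (summed
component weights, in detector counts), `ce_fraction` the droplet's
CE/(CE+TAG) composition. Here the generator placed NE droplets with a
+0.1 CE-fraction offset, and the full pipeline — unmixing, droplet
detection, NE classification — recovers that enrichment
(0.439 vs 0.363, Welch p ≈ 1e-05).

The same analysis runs end to end from a single config with
`run_pipeline(default_run_config(out_dir = "out", seed = 1))`, which
writes droplet/cell CSVs, reference spectra, a weights TIFF, a
false-color PNG (TAG magenta, CE green, saturated/unsegmented pixels
gray) and a run log. A thin command-line wrapper ships at
`inst/cli/srsld` (`srsld synth|all --out DIR --seed N`).

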