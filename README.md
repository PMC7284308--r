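# mtphen

Quantitative phenotyping of 3D cardiac microtissues (MTs) — scaffold-free
spheroids aggregated from hiPSC-derived cardiomyocytes (CM), endothelial
cells (EC) and cardiac fibroblasts (CF).  MT studies ask structural and
functional questions at once: how nuclei pack and which cell types are
where (confocal stacks), how well sarcomeres align (ACTN2 striations),
how the tissue contracts and whether it follows pacing (bright-field
movies), and how mature the electrophysiology and calcium handling are
(voltage and fluorescence traces).  mtphen implements the whole
quantification chain as composable R functions, plus a synthetic-data
module that generates every input with exact analytic ground truth, so
each stage is testable without a microscope.

## What it computes

* **Nuclei segmentation** — per-slice chain scaled by a single kernel
  radius KR (lighting homogenization by opening subtraction, local-median
  background removal, median/Gaussian/maximum enhancement, EDT seeding,
  nearest-seed flood fill, KR² size filter, oversize splitting).
* **3D reconstruction** — moment-fit ellipses linked across z by
  rasterized ellipse overlap (greedy maximal-overlap, one-to-one), with a
  condition-specific axial cap KZ; ellipsoid fits give per-nucleus volume
  V = (4/3) π a b c.
* **Cell-type classification** — per-section marker intensities
  (TNNI → CM, COL1A1 → CF, CD31 → EC) inside the fitted ellipses, modal
  vote over sections; presence/absence scoring for Ki67 (proliferation)
  with fiber removal by a 135° line opening and a mean + SD background
  cut.
* **Spatial packing** — per-nucleus median distance to its 12 nearest
  neighbors and the MT-level mean ± SD.
* **Sarcomere organization** — FFT power-spectrum alignment index (area
  under the first-order periodicity peak over total spectral area) and
  Z-band spacing with sub-pixel peak refinement.
* **Contraction** — Horn–Schunck dense optical flow, 15 × 15 µm binning
  over a 300 × 300 µm selection, max-bin contraction/relaxation profiles,
  five per-beat kinematic parameters, direction maps,
  normalized contraction duration = cd / √IBI, and a pacing classifier
  (rate within ±15% of pacing and amplitude CV < 28%).
* **Traces** — AP features (RMP, APA, APD90, Vmax), I_to-notch detection
  (minimum post-peak derivative < −3 mV/ms), dF/F with mean + SD tissue
  masking, calcium transient kinetics, and the caffeine amplitude ratio.

## Worked example

Generate a synthetic spheroid stack with known ground truth, run the full
nuclei pipeline, and summarize composition and packing:

```r
library(mtphen)
g <- generate_stack(stack_recipe(n_nuclei = 60,
                                 dim_zyx = c(30L, 160L, 160L), seed = 5))
segs   <- segment_stack(g$stack, "dapi", seg_params(kr = 5))
nuclei <- link_objects(segs, kz = kz_lookup("d21_with_fibroblasts"))
length(nuclei)
#> [1] 62

tab <- nuclei_table(nuclei, 0.5, 1)
head(tab[, c("id", "z_min", "z_max", "n_sections", "cx_um", "cy_um", "cz_um")], 3)
#>   id z_min z_max n_sections     cx_um     cy_um cz_um
#> 1  1     2     6          5 48.271493 73.783032   3.5
#> 2  2     3     6          4 45.322688  8.019542   4.0
#> 3  3     3     7          5  4.909403  7.694310   4.5

markers <- prepare_markers(g$stack, kr = 5)
comp <- composition(classify_nuclei(nuclei, markers))
round(comp$pct, 1)
#>   CF   CM   EC
#> 15.3 69.5 15.3

avg <- mt_average_distance(
  knn_median_distance(as.matrix(tab[, c("cx_um", "cy_um", "cz_um")]), 12))
round(avg, 2)
#>  mean    sd     n
#> 19.29  2.60 62.00
```

The 60 planted nuclei are recovered as 62 3D objects (the ground truth in
`g$truth` lets you score counts, centroids, identities and Ki67 flags
directly), the generated 70/15/15 CM/EC/CF composition is recovered
within a couple of percentage points, and nuclei sit ~19 µm apart — the
spacing implied by the generator's packing density.  The same pattern
applies to the other modules: `generate_movie()` →
`optical_flow()` → `bin_and_select()` → `profile_parameters()` /
`classify_pacing()` for contraction, and `generate_ap_trace()` /
`generate_calcium_trace()` → `ap_features()` / `detect_notch()` /
`transient_kinetics()` / `caffeine_ratio()` for traces.

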