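---
title: "Quantifying 3D cardiac microtissues: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D cardiac microtissues: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphen)
```

mtphen quantifies scaffold-free 3D cardiac microtissues (MTs) -- spheroids
of a few thousand hiPSC-derived cardiomyocytes (CM), endothelial cells
(EC) and cardiac fibroblasts (CF) -- from three kinds of raw data:
multichannel confocal stacks of stained nuclei, bright-field movies of the
beating tissue, and sampled voltage or fluorescence traces.  This vignette
explains the models and procedures behind each stage, the parameters that
matter, and the design decisions taken where the underlying methods leave
choices open.  Every quantitative claim made here is one the package's own
test suite computes.

## The kernel radius

All 2D image operators are scaled by a single kernel radius, KR, chosen as
the minimal radius (in pixels) of the objects of interest.  For MT nuclei
imaged at about 0.5 um/px the working value is KR = 5.  Derived scales
used throughout: the lighting-homogenization opening uses a disk of radius
5 KR, the local-background median a square window of side 8 KR, the
enhancement median/maximum filters radius KR, the Gaussian blur SD KR/2,
and the minimum retained object area is KR^2 px.

## Nuclei segmentation (per slice)

Each z-slice of the DAPI channel passes through six steps:

1. **Lighting homogenization** -- subtraction of the grayscale
   morphological opening with a disk of radius 5 KR.  Removes lateral
   illumination trends while preserving objects smaller than the disk.
2. **Local background subtraction** -- pixels at or below their local
   median (square window, side 8 KR) are zeroed; the rest keep value
   minus local median.  The window must exceed the nucleus diameter so
   the local median reads background, not object.
3. **Enhancement** -- median filter (radius KR), Gaussian blur (SD KR/2),
   then a grayscale maximum filter (disk KR), consolidating each nucleus
   into a compact bright plateau.
4. **Binarization** -- foreground is everything above the slice median
   plus 5 MAD.  On integer images whose background majority is exactly
   zero, median and MAD both vanish and this reduces to the plain
   median-threshold rule the operator sequence was designed around.  On
   continuous-valued (float) images a bare median threshold necessarily
   marks half of every slice as foreground, so a noise allowance is
   required; the multiplier 5 was fixed by a null calibration -- the
   smallest integer multiple leaving zero false objects on
   background-only slices -- and sits an order of magnitude below nuclear
   intensities.
5. **Seeding** -- Euclidean distance transform (EDT) of the foreground;
   seeds are EDT local maxima thinned to a minimum mutual separation of
   KR (ranked by EDT value, ties broken in column-major pixel order).
6. **Flood fill and size rules** -- the foreground is partitioned among
   seeds by nearest-seed geodesic growth (realized with a constrained
   propagation, which is deterministic and order-independent).  Objects
   below KR^2 px are discarded.  An object with area at least
   n x (split threshold), n = floor(area / threshold) >= 2, is re-seeded
   with its n strongest interior EDT maxima and re-partitioned.  The
   split threshold is user-set (2-3x the median section area is a
   sensible scale) and disabled by default.

Objects touching the image border are kept: in real MT data the spheroid
fills the frame.

The enhancement maximum filter dilates every object boundary by about KR.
This is intentional -- it closes holes and stabilizes seeding -- but it
means segmented areas overestimate nuclear footprints; the downstream
stages that sample intensities or fit volumes correct for it explicitly
(below).

## 3D reconstruction

Per-slice objects are reduced to their moment-fit ellipses (second central
moments with equal-area normalization, pi a b = area; orientation in
(-pi/2, pi/2]).  Two objects in adjacent slices *interact* when their
rasterized ellipses share at least one pixel.  Chains are built slice by
slice: an object with no interaction in the previous slice starts a new 3D
object; otherwise chains elongate to the interacting candidate of maximal
shared area, matched one-to-one greedily by descending shared area (ties
to the smaller object index).  A chain reaching KZ slices -- the
condition-specific maximal axial extent (18 for day-7/21 MTs without
fibroblasts, 10 with fibroblasts, 46 for CMECs, 36 otherwise) -- closes,
and any continuation starts a new object.  KZ is a maximum only; no
minimum length is imposed.

Greedy one-to-one matching was chosen because the overlap rule alone does
not define what happens when two chains compete for one section; greedy
matching is deterministic and easily checked against an oracle.  A known
limitation follows from the any-overlap interaction rule: when two nuclei
sit close laterally and meet end-to-end in z, the dilated ellipse of a
chain's last section can overlap the first section of the next nucleus
and bridge the two into one chain.  Under the default synthetic
conditions this affects a few percent of nuclei and is the main
contributor to the count error.

### Volume

An ellipsoid is fitted per chain: the in-plane semi-axes are the
section-area-weighted means of the 2D semi-axes, the axial semi-axis is
half the chain extent, and volume is (4/3) pi a b c.  Two corrections
matter:

* **Shape correction.**  For a true ellipsoid sampled by parallel
  sections, the area-weighted mean of the section semi-axes equals
  9 pi / 32 (about 0.884) of the equatorial semi-axis; without correction
  the estimator is biased about -22% in volume.  `fit_ellipsoid` divides
  the weighted means by 9 pi / 32 by default.
* **Dilation correction.**  Sections measured through the segmentation
  chain carry the ~KR boundary dilation of the maximum filter;
  `dilation_px` subtracts a known dilation from the per-section semi-axes
  before averaging.  It defaults to 0 because the effective dilation
  depends on object size and contrast; volume validation in the test
  suite therefore runs on ideal (un-dilated) sections of synthetic
  ellipsoids, where recovery is within 10%, and full-pipeline volumes
  should be read as relative, not absolute, measures.

## Cell-type classification

Marker channels (TNNI for CM, COL1A1 for CF, CD31 for EC) are smoothed
(Gaussian, SD KR/2) and normalized over the volume to
(x - median) / (max - median), clipped to [0, 1].  The median anchors the
background at zero because nuclei occupy a minority of voxels.  Plain
min-max normalization was rejected: a channel whose marker stains no cell
in the tissue would stretch pure noise across [0, 1] and its in-ellipse
means (~0.4) would pass any sensible threshold.  With the anchored
normalization, classification remains invariant to per-channel gain and a
stain-free channel normalizes to small values.

Per section, the mean normalized intensity of each marker is read inside
the fitted ellipse *eroded by KR*: sampling the raw (dilated) ellipse
dilutes the marker mean roughly four-fold with background.  The section
identity is the above-threshold marker of highest intensity (default
threshold 0.25 per channel, a user calibration in principle), or
unclassified if none passes.  The nucleus takes the modal section
identity; ties go to the higher mean intensity across the chain.  Every
nucleus gets exactly one label from {CM, EC, CF, unclassified}.

### Presence/absence scoring (Ki67, COL1A1)

Proliferative (Ki67+) and fibroblast (COL1A1+) cells are scored by a
presence pipeline: per slice, a grayscale opening with a 135-degree line
element removes fibrous structures, then Gaussian blur (SD KR/2) and
lighting homogenization; all pixels below the channel mean plus SD are
zeroed, and surviving connected specks smaller than KR^2 px are removed.
A nucleus is positive when the mean processed intensity inside its eroded
section ellipses is strictly greater than zero.

Three choices here deserve explanation.  The line element is 2 KR long at
most (and odd): a longer line cannot fit inside a minimal nucleus
(diameter 2 KR by the definition of KR) and the opening would erase the
nuclei themselves.  The opening runs *before* the blur, at native
resolution, because blurring first widens thin fibers beyond any line
length that still spares nuclei.  And the mean + SD statistic is taken
over the whole channel rather than per slice: on a slice containing no
positive cell, a per-slice statistic describes pure background and lets a
fixed fraction of noise through, destroying specificity.

## Spatial packing metric

For each nucleus centroid (in calibrated micrometres), the distances to
its 12 nearest neighbors are collected and their median reported as the
nucleus's most probable neighbor distance; the MT-level summary is the
mean and SD (n-1 denominator) of the per-nucleus medians.  k is capped at
n - 1 for small samples, even-count medians average the two central
values, and neighbor ties break by index (the median is unaffected).  The
implementation agrees exactly with an all-pairs brute-force oracle, and on
a simple cubic lattice with spacing d the interior-nucleus median is
d (1 + sqrt(2)) / 2 -- six face neighbors at d and six edge neighbors at
d sqrt(2) make up the 12 nearest.

## Sarcomere organization

Z-band periodicity (ACTN2-like striations, physiological spacing about
1.8-2.2 um) is quantified from the power spectrum.  For a 2D image the
spectrum is collapsed along the dominant orientation -- every FFT bin's
power accumulates at the absolute projection of its frequency onto the
maximal-energy direction -- so disorder spreads energy across the
profile.  The **alignment index** is the fraction of profile power inside
the first-order peak: the dominant local maximum whose period lies in the
expected sarcomere band (default 1-3 um), with support a fixed relative
bandwidth of +-15% of the peak frequency.  A half-maximum support was
tried first and rejected: as the peak flattens into the surrounding
spectrum the half-maximum walk expands over neighboring near-equal bins
and the index rises again, breaking monotonicity in disorder.
Frequencies below 1/(10 um) are excluded from the denominator so
illumination gradients cannot leak into the total.  The index is bounded
in [0, 1] and invariant to intensity gain and offset.

**Sarcomere length** is the mean peak-to-peak spacing of Z-band intensity
maxima (plateau-tolerant peak detection, sub-pixel parabolic refinement),
cross-checked against the reciprocal of the dominant spectral frequency;
the two estimators must agree within 5% or a warning is raised.

## Contraction analysis

Dense motion between consecutive frames is estimated with the classic
Horn-Schunck variational method: brightness constancy balanced against
field smoothness, spatiotemporal derivatives over the 2x2x2 cube, Jacobi
updates with the standard 1/6-1/12 neighbor-average kernel, zero
initialization, 100 iterations.  The regularization weight is relative to
image contrast; the default alpha = 0.05 corresponds to the classic
8-bit-era setting rescaled to unit-range frames (with alpha = 1 on unit
frames the data term is so weak that 100 iterations recover only a
quarter of a half-pixel translation).  Frames are mean-normalized first
to damp global illumination flicker.  Flow on identical frames is exactly
zero.

Speeds are calibrated as |v| x um/px x fps and averaged in 15 x 15 um
bins over a 300 x 300 um selection (both configurable; the selection must
fit the frame).  The analysis bin is either user-chosen or fixed
automatically as the bin maximal at the recording's global peak frame --
fixing one bin for the whole recording keeps the profile continuous,
which per-frame re-selection does not.  Per-bin SDs across vectors are
retained alongside the profile.

From the max-bin speed profile, beats are the contiguous epochs above 10%
of the profile maximum (crossings linearly interpolated; the threshold
fraction is configurable).  Each beat yields five parameters: upstroke
velocity and acceleration (contraction phase), relaxation velocity and
acceleration, and beat duration; two-hump beats split phases at the
interior minimum, single-hump beats at the peak.  At least five beats are
required by default.  Contraction direction is atan2(v, u) per vector,
with zero vectors masked.  Normalized contraction duration is
cd / sqrt(IBI).

The pacing classifier estimates rate as (n - 1)/(t_last - t_first) from
the beat times -- an interval estimator suited to short (~10 s)
recordings -- and declares that a tissue follows stimulation when the
rate is within +-15% of the pacing rate *and* the amplitude coefficient
of variation (SD with n-1 denominator over mean) is below 28%, a cutoff
accommodating random amplitude variation.  The CV is scale-free, so the
units of the contraction amplitude do not affect the verdict.

## Trace analytics

**Action potentials.**  Upstrokes are detected where dV/dt exceeds 5 V/s
for at least 1 ms.  Per beat: RMP is the mean diastolic voltage over the
50 ms before the upstroke; APA = peak - RMP; Vmax is the maximal upstroke
derivative (mV/ms = V/s; ties resolve to the last occurrence so a linear
ramp reports its end); APD90 runs from the Vmax instant to the first
interpolated crossing of peak - 0.9 APA.  Features average across beats.
Note that with short pacing periods the repolarization tail raises the
diastolic window of subsequent beats slightly; exact fixture checks use a
single beat or periods long enough for complete repolarization.

**I_to notch.**  The voltage is smoothed with a 3-sample moving mean,
differentiated in mV/ms, and the minimum derivative within the peak
region (peak to peak + 50 ms) is compared to a cutoff of -3: below it,
the AP carries a notch.  The cutoff absorbs random trace oscillation; its
units (mV/ms), the smoothing width and the window are configurable since
the underlying convention leaves them open.

**Calcium.**  For movies, the tissue mask is the maximum projection
thresholded at its overall mean + SD; F(t) is the in-mask mean minus the
mean of a user-selected background region outside the tissue; F0 is the
mean of the lowest-decile frames (a baseline robust to transients
occupying most of the record), and dF/F = (F - F0)/F0 -- invariant to
background offset and global gain.  Transient kinetics (time to peak from
the 10%-amplitude onset; peak to 50% and to 90% decay) are interpolated
per transient and averaged; a transient whose 90% decay is not reached is
excluded with a warning.  The caffeine ratio divides the first
post-caffeine peak amplitude by the mean of the four preceding peak
amplitudes, each measured from its local baseline; peaks with local
amplitude under 20% of the largest are treated as noise bumps on decay
tails and discarded before baselines are re-measured.

## The synthetic-data module

Every pipeline input can be generated with exact, analytically emitted
ground truth (never re-measured from the rendered data), and identical
recipes and seeds reproduce outputs bit for bit; all randomness flows
through one seeded generator per call and the caller's RNG state is
restored.

* **Stacks** place ellipsoidal nuclei (in-plane semi-axes 2.5-3.5 um,
  axial 2-3.5 um, in-plane orientation only) by rejection sampling with a
  hard minimum center spacing, 10 um by default -- the scale of a
  cardiomyocyte cell body, and consistent with the segmentation's
  assumption of separable nuclei.  The default field is 256 x 256 px at
  0.5 um/px with 44 slices at 1 um, holding 200 nuclei at a packing
  density rejection sampling fills comfortably.  Identities follow the
  70/15/15 CM/EC/CF composition of fibroblast-containing MTs by exact
  deterministic allocation (floor plus largest-remainder); 20% of nuclei
  are Ki67+.  Markers paint the nuclear footprint (the classifier reads
  nuclear ellipse sections, so cytoplasmic rendering is out of scope).
  Imaging artefacts: a planar multiplicative illumination ramp, per-slice
  exponential z-attenuation, additive Gaussian noise (default SD 10% of
  the nuclear intensity), and optional 45-degree fibrous streaks on the
  Ki67 channel as classification distractors.
* **Striation images** are sinusoids of known period whose local
  orientation is perturbed by a smooth Gaussian field of requested
  angular SD; jitter 0 is globally coherent, large jitter approaches
  isotropy.
* **Movies** warp a smoothed random texture by the cumulative ground-truth
  displacement (bilinear interpolation): constant translation, or a train
  of Gaussian velocity pulses (one per period), optionally confined to a
  smooth circular active patch.  Per-step true velocities are returned.
* **Traces**: piecewise-analytic APs (baseline, linear upstroke, optional
  linear notch dip, exponential repolarization whose time constant is
  solved so the true APD90 is exact); beat series whose amplitude CV is
  exact after affine rescaling; calcium transients with linear rise
  (time-to-peak defined 10%-to-peak, like the measurement) and
  single-exponential decay, so peak-to-50% = tau ln 2 and peak-to-90% =
  tau ln 10 in closed form.

What the generator does *not* emulate -- and what passing tests therefore
do not establish about real data: optical point-spread blurring and
z-bleed between slices, cytoplasmic marker localization, chromatin
texture inside nuclei, nucleus-shape irregularity, motion blur, shot
(Poisson) noise, and drift or focus changes during movies.  Recovery
rates measured on the synthetic conditions characterize the algorithms
under their stated assumptions, not microscope performance.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data:
one 200-nucleus stack (256 x 256 x 44 voxels) drives the segmentation,
reconstruction and classification checks; flow checks use 96-128 px
movies of about a dozen frames; trace checks use single-second recordings
at 1-10 kHz.  These sizes keep a full run in tens of seconds while
leaving every stage's accuracy measurable.  `scripts/acceptance.R` (see
the README) regenerates all inputs from a command-line seed and recomputes
the headline quantities from scratch.
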