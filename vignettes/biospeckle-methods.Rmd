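---
title: "Quantifying nematode bioactivity from biospeckle light-sheet scans"
author: "bspim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nematode bioactivity from biospeckle light-sheet scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspim)
```

## The measurement

When coherent laser light passes through living tissue, interference
produces a grainy "speckle" pattern. Tissue that moves or is metabolically
active scrambles the optical path lengths from frame to frame, so the
speckle *dances*; dead or static material produces a frozen pattern. In
biospeckle selective plane illumination microscopy (BSPIM), a cuvette
holding nematodes suspended in a colloid/water mixing layer is stepped
through a laser light sheet; at every stage step a burst of T brightfield
frames is captured. The temporal decorrelation of each pixel over the
burst is the local bioactivity signal.

`bspim` turns these scans into quantitative screening readouts: how active
is a sample of worms, how does that activity change after a chemical
treatment, and does the shape of the activity trace distinguish motile
from stationary trophic groups.

## From frame bursts to an activity volume

**Generalized differences.** Each burst is reduced to a 2D activity map by
summing absolute grey-level differences over all frame pairs,

$$GD(p) = \frac{2}{T(T-1)} \sum_{k<l} \left| I_k(p) - I_l(p) \right|,$$

with the pair-count normalization as the default so values stay on the
grey-level scale — that keeps the grey-level detection threshold
meaningful. The raw sum is available via `normalization = "sum"`. The
implementation uses the sorted-value identity
$\sum_{k<l}|a_k-a_l| = \sum_j (2j-1-T)\,a_{(j)}$, which is
$O(T\log T)$ per pixel; tests verify it against the direct double loop to
$10^{-9}$. Identical frames give an exactly zero map and the map is
invariant to frame order.

**Volume assembly and filtering.** Per-step maps are stacked along the
stage axis into a voxel volume with anisotropic voxel sizes (in-plane
pixel pitch vs. the 62.5 µm stage increment). Voxel sizes are carried as
metadata and never resampled, because resampling would change the voxel
counts reported as biospeckle volume. The filtering chain runs in a fixed
order:

1. **Crop** to a region of interest containing the mixing layer.
2. **Background subtraction** with a 2 mm physical radius. The smooth
   background of each slice is estimated by grayscale morphological
   opening with a flat disc (the flat-structuring-element equivalent of
   rolling-ball subtraction) and subtracted, clipping at zero. The radius
   is converted to pixels through the manifest pixel size; it is an
   in-plane length, and background estimation is 2D per slice because the
   stage spacing is one to two orders of magnitude coarser than the pixel
   pitch. The opening is computed by decomposing the disc into its
   horizontal chords with logarithmic-time running minima/maxima; border
   pixels use only the in-bounds part of the disc, so a spatially uniform
   slice maps exactly to zero.
3. **Median filter**, per-slice, radius 1 px by default — the smallest
   window that suppresses shot noise; edges are handled by reflection.
4. **3D Gaussian blur**, sigma (1, 1, 1) voxels by default, as a
   separable convolution with an integer-sampled kernel normalised to
   unit sum (support radius $\lceil 4\sigma \rceil$), so an interior
   point source conserves its total intensity; sigma 0 on an axis is the
   identity.

The median radius and Gaussian sigma are not dictated by the acquisition
protocol, so both are exposed in `bspimConfig()`; users should match them
to their own optics.

## Objects and descriptors

Voxels strictly above the intensity threshold (default 20 grey levels)
form the foreground; connected components under 26-connectivity (the 3D
object-counter convention; 6 available) of at least 20 voxels are
retained. Both the strict inequality and the inclusive size filter are
deliberate readings of the protocol: an object of exactly 20 voxels
survives, a voxel at exactly grey level 20 does not. Labels are assigned
in raster order of each component's minimum voxel index so outputs are
reproducible byte for byte. Components are found by label-minimum
propagation over the foreground adjacency; the test suite checks exact
agreement with an independent breadth-first flood fill.

Per object $i$ the pipeline reports the **biospeckle volume**
$N_i = n(\Omega_i)$ (voxel count — body size plus space explored during
the scan) and the **biospeckle intensity**
$I_i = \frac{1}{N_i}\sum_{X_j \in \Omega_i} X_j$ (mean grey value —
internal activity and fast movement). The sample-level readout is the
**total biospeckle intensity** $\mu = \sum_i I_i$, which is 0 exactly
when nothing is detected.

**Shape descriptors.** Each object is projected onto the XY plane (facing
the objective) and the YZ plane (perpendicular to the light sheet). The
projection mask is the set of pixels hit by at least one object voxel;
the projected intensity is the maximum along the collapsed axis — a
deterministic, automatable stand-in for the interactive 3D-viewer
workflow. For YZ the z axis is rescaled by voxel$_z$/voxel$_y$ before
hull fitting (`physical_aspect`, default on), since stage steps are much
coarser than pixels. A convex hull is fitted to the pixel centres and the
**circularity**

$$C_A = 4\pi S / P^2$$

is computed from hull area and perimeter; 1 is a perfect circle, and the
drawn-out traces of motile worms give low values. Degenerate masks (fewer
than three distinct points, or collinear) are padded by a half-pixel
square per pixel so the perimeter stays positive and $C_A$ defined for
tiny objects. The **minimum circularity** over the two planes is the
shape readout; the **integrated density** is the sum of projected grey
values over the mask.

## Screening statistics

Each replicate is its own baseline: the total biospeckle intensity at 2 h
and 24 h after treatment is expressed as a percentage of the same
replicate's pre-treatment value, $100\,\mu_t/\mu_0$. Replicates with a
zero baseline have no defined percentage and are excluded with a logged
warning, never silently. Two-sided paired t-tests compare the raw
intensities at each post-treatment time against the pre-treatment scan;
shape contrasts between treated and untreated worms use two-sided
unpaired t-tests (equal-variance by default, Welch by flag). Raw p-values
are reported with no multiple-testing correction, matching the original
analysis protocol; whether the original tests were one- or two-sided is
not stated, so two-sided is assumed. Zero-variance degeneracies
(identical vectors; a constant shift) are handled explicitly before
dispatching to `t.test`, which would otherwise error: identical data give
t = 0, p = 1, and a constant non-zero shift is reported as the p → 0
limit with a warning.

## The synthetic scan simulator

Real scans of soil nematodes are not deposited anywhere, so the package
ships a simulator whose *statistical* contract matches what the pipeline
measures; it makes no attempt at coherent-light physics.

* **Speckle model.** The background is fully developed static speckle
  (exponential intensity, mean 60, contrast 0.5) plus per-frame Gaussian
  sensor noise (sd 2), quantised to 8 bits. Pixels occupied by a worm
  carry their own speckle field (mean 130) which is redrawn between
  frames with probability `activity × decorrelationScale`. The scale
  (default 0.2 per frame) keeps a burst of T = 16 frames from saturating:
  with a redraw probability near 1 almost every frame pair differs and
  the generalized differences stop responding to activity. Moving body
  parts decorrelate regardless, because pixels entering or leaving the
  footprint change value by occupancy alone. A worm with activity 0 and
  speed 0 is statistically indistinguishable from background.
* **Worm model.** A worm is a thickened sinusoidal centerline with
  trophic-group presets: bacterial feeders undulate smoothly (wavelength
  0.8 body lengths, amplitude 2 px) with an oscillating head and
  translate at 0.3 px/frame; worms swim in three dimensions, so a
  fraction (0.15 slices per pixel of speed) of the translation goes into
  drift along the stage axis, bouncing at the mixing-layer boundaries —
  this is what draws out a motile worm's trace in the YZ projection as
  well as in XY; plant feeders move sporadically through a
  two-state move/pause chain (start 0.08, stop 0.15 per frame) with
  short-wavelength, high-amplitude undulation and no head oscillation;
  Trichodorus worms are alive but nearly stationary (activity 0.75,
  speed 0.02 px/frame) and hold a curled, compact posture, as stationary
  worms do. Head oscillation is active motion and stops in dead worms.
  No quantitative motility rates per group are published; preset speeds
  are order-of-magnitude choices exposed in the constructors, not claims
  about real nematodes.
* **Scene conditions.** The default scene is 5 worms in a
  64 × 64 × 10 voxel volume (25 µm pixels, 62.5 µm steps), worms placed
  in a mixing-layer band of slices 3–7, 16 frames per step. The worm's
  effective thickness along the stage axis is 2.5 steps, reflecting the
  ~1 mm light-sheet thickness rather than the worm diameter. All
  randomness flows from a single seed in a fixed draw order, so scans are
  byte-reproducible.
* **Toxin model.** `scaleWormActivity()` multiplies activity and
  motility by separate factors because toxins typically suppress
  movement before internal activity ceases.

## Desk-scale study conditions used by the tests

The acceptance checks run entirely on simulated scans, at sizes chosen to
make the suite complete in minutes on a single core:

* *Activity recovery, dead-worm null, live detection*: the default
  64 × 64 × 10 scene at T = 16, 20 seeds per condition.
* *Shape contrasts* (stationary vs. motile, knock-down): one worm in a
  96 × 96 × 8 scene, so a motile trace never reaches the walls; 20 seed
  pairs.
* *Screening power*: a wide field of view — 160 × 160 px at 50 µm/pixel
  (an 8 mm field), depth 5, T = 8 — in which 5 worms remain resolved as
  separate objects, as they are in the cuvette assay where worms are
  separated by many body lengths. In a deliberately cramped field,
  active worm traces merge into a single object and the sum-of-means
  readout $\mu$ loses its meaning; the wide field is fidelity to the
  assay geometry, not a tuning knob. The simulated 24 h knock-down
  multiplies activity and speed by 0.4; 25 repetitions of 5 replicates.

What passing these tests shows — and does not show. The simulator
demonstrates that the pipeline recovers activity ordering, separates
dead from live worms at the published thresholds, reproduces the
stationary-worms-are-more-circular shape finding, and detects a strong
knock-down with the paired design at n = 5. It does not validate the
optics: real speckle has spatial correlation structure, partially
developed statistics, and depth-dependent scattering that the simulator
does not model, and real nematode motility is far richer than a
sinusoidal centerline. Quantitative values measured on real scans (e.g.
the regressions of biospeckle volume on intensity) are not reproducible
from synthetic data and are not claimed.

## Numerical choices and edge cases

* Grey values are normalised to numeric in memory; raw integer data are
  preserved on disk (8-bit TIFF by default, bit depth recorded in the
  manifest; no contrast correction is applied since the acquisition bit
  depth handling is not published).
* Coordinates are 0-based with x along image width, y along height, z
  along the stage axis; voxel (0, 0, 0) is the top-left pixel of the
  first step. All exported coordinates follow this convention.
* The background radius is taken as a physical length and converted
  through the pixel size (the protocol does not say whether the original
  2 mm was physical or a pixel count); radii beyond the slice diagonal
  are capped there, where the opening no longer changes.
* The voxel-level threshold and the object-level brightness cut are
  applied as one voxel-level threshold; the published description is
  ambiguous about whether they were distinct.
* Selection of individual nematodes for shape analysis was a manual step
  in the original workflow; here it is the caller's choice of object
  identifiers, not an algorithm.
* Empty volumes detect zero objects ($\mu = 0$) without error; empty
  projections, zero perimeters and n < 2 test inputs raise informative
  errors.

## A worked example

```{r example, eval = FALSE}
library(bspim)

# simulate a 5-worm sample and a 24 h knock-down of the same sample
scene <- sceneSpec(width = 160L, height = 160L, depth = 5L,
                   mixingLayerZ = c(1, 4), framesPerStep = 8L,
                   pixelSizeUm = 50)
worms0 <- replicate(5, wormPreset("bacterial_feeder"), simplify = FALSE)
worms24 <- lapply(worms0, scaleWormActivity, factor = 0.4)

mu <- function(worms, seed) {
  scan <- simulateScan(scene, worms, seed)
  dir <- tempfile()
  m <- readScanManifest(writeScan(scan, dir))
  totalBiospeckleIntensity(runSample(m)$result)
}
mu0 <- vapply(1:5, function(k) mu(worms0, 100 + k), numeric(1))
mu24 <- vapply(1:5, function(k) mu(worms24, 200 + k), numeric(1))
pairedTTest(mu0, mu24, label = "24h_vs_0h")
```
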