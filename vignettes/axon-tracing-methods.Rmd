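---
title: "Automated axon tracing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated axon tracing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axontracer)
```

## The problem

Quantifying regenerating or sprouting axons in fluorescence images of
nervous tissue -- for instance corticospinal tract (CST) collaterals growing
into a neural-progenitor-cell graft after a spinal cord lesion, or sprouting
within spinal grey matter delineated by NeuN staining -- requires two
decisions per image: *where* to count (the region of interest, ROI) and
*what* counts as an axon. This package automates both as a headless batch
pipeline over folders of RGB microscope images, with a seeded synthetic
image generator standing in for tissue so that every stage is testable
against known ground truth.

An analysis folder contains only image files (TIFF/PNG/JPEG) whose names are
plain positive integers without leading zeros (`3.tiff`, `24.jpeg`, ...).
Images are processed in ascending numeric order with one frozen parameter
set, which keeps quantification identical across experimental groups. The
tool's own outputs (the `traced images` folder and the summary spreadsheet)
are recognized and ignored when the folder is re-scanned, so a folder
remains a valid analysis folder after a run.

## Region of interest

Four modes differ only in how the ROI mask is made:

1. **Entire image** -- every pixel.
2. **Automatic ROI** -- segmented from a designated color channel
   (e.g. a dsRED-labeled graft, or NeuN-stained grey matter).
3. **Manual ROI, one axon channel** -- a user polygon (CSV of `x,y` vertices,
   0-based, origin top-left; rasterized inclusively, so the rectangle
   (10,10)-(20,20) covers 11 x 11 pixels).
4. **Manual ROI, two axon channels** -- the same polygon applied to two
   axon channels.

Automatic segmentation is a fixed sequence:

* *Contrast stretch*: linear stretch saturating 0.35% of pixels at each
  tail. The saturation fraction is the common default of the imaging
  platforms this models; it is a display-normalization step, so its exact
  value is uncritical.
* *Binarization*: Otsu's threshold on the stretched plane (bright =
  foreground). Two degenerate rules are explicit: an exactly constant plane
  is cut at mid-scale 127 (so an all-dark plane is empty and an all-bright
  plane is full), and a near-constant plane -- stretch window narrower than
  32 intensity levels -- is treated as carrying no ROI signal at all.
  Without the second rule, Otsu on a noise-only channel binarizes roughly
  half the pixels and a signal-free image would grow a large spurious ROI
  instead of being reported empty.
* *Particle removal*: 8-connected components smaller than `minParticlePx`
  (default 100 px) are debris.
* *Hole filling*: background regions (4-connected) not touching the frame
  border are filled.
* *Enlarge/reduce*: Euclidean-distance dilation by `enlargePx` (default 60)
  followed by erosion by `reducePx` (default 90). "Enlarged by N" is read
  as inclusive distance-transform morphology (a pixel joins if its distance
  to the region is <= N), not as iterating a structuring element; under
  this reading two fragments merge exactly when their gap is at most
  2 x 60 = 120 px, and the net 30-px reduction removes isolated fragments
  of half-width below 30 px -- the two constants the automated sweep in
  `scripts/acceptance.R` reproduces. During the sequence the mask is padded
  so regions may transiently extend past the frame; consequently the frame
  border behaves like background for erosion (a full-bright frame ends up
  eroded by the net 30 px).
* *Adjustment*: a final user dilation/erosion of `adjustPx` in -255..255,
  applied after the merge sequence (whether the original applies it before
  or after is not documented; after is the conservative choice since it
  leaves the merge constants untouched).

For batch tuning, the *parameter image* is the one whose ROI channel has
the median mean intensity (lower median for even counts, ties to the lowest
id) -- a representative, neither the dimmest nor the brightest.

## Axon detection

Inside the ROI (cropped to its bounding box, outside pixels zeroed):

1. **Tissue-hole repair.** Holes -- 8-connected regions with intensity at
   most `holeIntensityMax` (default 5) and area at least `holeMinAreaPx`
   (default 500; both chosen for typical sectioning artifacts, neither is
   critical) -- are filled with the mean intensity of the remaining tissue
   (rounded half-up). Their sharp edges would otherwise be detected as
   axons. The hole defaults are deliberately permissive; the
   zeroed-out region outside an irregular ROI is treated the same way,
   which also suppresses edge artifacts along the ROI boundary.
2. **Ridge response.** Second-order Gaussian-scaled derivative along x and
   along y (sampled derivative-of-Gaussian kernel, zero-sum corrected,
   smoothed with a plain Gaussian across the axis), sign-inverted so bright
   curvilinear structures respond positively, then min-max normalized to
   [0, 1] per axis. The derivative scale defaults to 1 px and should be
   matched to fiber width (sigma ~ w / sqrt(3); 1.7 px for the 3-px
   fixtures below).
3. **Thresholding.** A pixel is detected when its normalized response is
   positive and at least `1 - sensitivity`. Because the normalization is
   relative, a plane with *no* signal would have its noise amplified to
   span [0, 1]; a guard therefore requires the strongest raw response to
   exceed that of a synthetic 1-px line of `minRidgeContrast` intensity
   levels (default 32) at the configured scale. Measured on the synthetic
   model, background noise of sd 8 peaks near 7.4 response units, a
   32-level line at 11.1 and tissue-hole edges at 15.9, so the guard
   separates "nothing to trace" from real structure while leaving the
   relative threshold semantics untouched.
4. **Skeletonization.** The x and y detections are combined by union
   (intersection would lose fibers parallel to one axis) and thinned to a
   topological skeleton: Zhang-Suen parallel thinning, a sequential pass
   that removes residual 2x2 blocks (only provably simple points are
   deleted, so connectivity is preserved), and removal of redundant
   city-block staircase corners. The result is guaranteed free of 2x2
   blocks. The 2-px diagonal chains that parallel thinning can leave are
   deliberately kept: table-driven skeletonize implementations on the
   imaging platforms this pipeline models leave them too, and their
   surplus pixels partially cancel the undercount that pixel counting
   suffers on diagonal runs (an ideal digital line at 45 degrees holds
   only 0.707 pixels per unit length). With both effects the pixel count
   tracks true arc length to within a few percent on smooth curves of
   mixed orientation.
5. **Cleanup and measurement.** 8-connected skeleton components are kept
   only if strictly larger than `cleanupPx` pixels. The total length is the
   number of surviving skeleton pixels -- the raw measure reported as
   "total pixels per image"; it is not converted to a Euclidean polyline
   length. In detail mode each component becomes one axon record with a
   deterministic color (evenly spaced hues in raster order of first pixel),
   and per-axon lengths sum exactly to the total.

Detection length is *not* globally monotone in sensitivity: past the noise
floor the binarized band fuses into solid regions whose skeleton is
shorter, and at sensitivity near 1 the detection degenerates entirely. The
monotone guarantees are at the set level (higher sensitivity detects a
superset of pixels) and in `cleanupPx` (larger cleanup never yields more
length). Batch users should stay within the regime found with `preview`.

## Normalization

When enabled, the *reference image* is the one with the highest mean
intensity in the (first) axon channel; the mean intensity inside a
user-supplied polygon on that image becomes the divisor for every raw
length in the folder (`normalized = raw / mean`), correcting for labeling
efficiency between folders. With two axon channels the reference mean is
computed on axon channel 1 and divides both channels' lengths; the
original interactive tool does not document its behaviour for this case.

## Synthetic fixtures and what they do (not) show

`generateAxonImage()` draws `nAxons` smooth random curves -- constant-speed
paths whose heading performs a gentle random walk (curvature noise
0.015 rad per sqrt(px)) -- stroked at `axonWidthPx` (default 3 px, via
distance-transform dilation of the dense polyline), intensity 200 over
Gaussian background noise (mean 30, sd 8), inside a 640 x 640 frame with
default 20 curves of 200 px each. Arc length is accumulated analytically
while the curve is built (0.05-px steps), so the truth is exact by
construction. Curves keep 25 px from the border and 12 px from each other
(rejection sampling with bounded retries), are non-self-intersecting at
these curvature settings, and therefore one traced component corresponds to
one curve. The graft channel places bright square blobs (intensity 200
over mean-10 noise) plus seeded debris specks; tissue holes are zeroed
rectangles. All randomness derives from the fixture spec's single seed.

The accepted detection parameters for this fixture class -- sensitivity
0.42, derivative scale 1.7, cleanup 20 -- were fixed once by tuning on a
parameter image, exactly the workflow the batch tool prescribes, and are
used unchanged by the test suite and acceptance script. Under these
conditions traced length recovers the analytic truth of twenty 200-px
curves to well within 10% across seeds, and detail mode reports exactly
twenty components.

The generator emulates the *geometry* the pipeline cares about: bright
curvilinear structures over noise, fragmented blob signal, holes and
debris. It does not model out-of-focus light, shot noise, intensity
variation along an axon, crossing or branching fibers, or high-dynamic-
range scenes with both bright and faint axons; passing tests therefore
validate the algorithmic chain, not detection performance on such tissue.
Crossing-fiber resolution and geodesic distance measures are out of scope.

## Numerical and interface choices

* Grayscale planes are H x W matrices on the 0-255 scale; 16-bit input is
  min-max rescaled at load, grayscale replicated to three planes.
* Problem sizes used by the checked-in tests: 640 x 640 for the recovery
  study, 256-320 px frames for batch and hole tests, sweeps over 41 gap
  widths and 60 half-widths at the reference 300 x 300 blob geometry.
* Hole-fill value rounds half-up; mean computed over non-hole pixels only.
* Component labeling is 8-connected for foreground, 4-connected for
  background (hole filling); labels are assigned in raster order, making
  every labeling, color assignment and output byte-deterministic.
* Spreadsheets are written as CSV (`tracing data summary.csv`, and in
  detail mode one `<id> Tracing Data Details.csv` per image, rather than a
  same-named sheet per image, which would collide headlessly).
* Result images mirror the input container; overlays for JPEG inputs are
  written as PNG so trace pixels stay exact. Per image `N`: `Na` original
  RGB with the ROI outlined in white, `Nb`/`Nc` cropped grayscale and
  yellow-trace overlay for axon channel 1, `Nd`/`Ne` the same for channel
  2, multicolor detail tracings under `Traced Images Detailed Results`.
* Per-image failures are recorded in the summary row (`status` column) and
  the batch continues; an empty ROI yields zero length, not a skip.
* Mixed image sizes within one folder are allowed; each image is analyzed
  independently.

## Known limitations

Pixel-count length has a residual orientation bias of a few percent even
with the staircase treatment above. Axons thinner than ~2 px or fainter
than the configured `minRidgeContrast` are invisible. A single polygon per
image is supported for manual ROIs. The interactive preview renders a
sub-rectangle of the parameter image but offers no GUI editing; parameters
are accepted by writing them to the run configuration.
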