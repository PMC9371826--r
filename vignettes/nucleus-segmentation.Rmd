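---
title: "Methods: foreground-marker watershed segmentation of H&E nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foreground-marker watershed segmentation of H&E nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucseg)
```

## The model

H&E staining is, to a good approximation, a linear process in optical
density. If `I_c` is the transmitted and `I0_c` the incident intensity in
channel `c`, the per-channel optical density `OD_c = -log10(I_c / I0_c)`
is the sum over stains of (stain amount at the pixel) × (the stain's unit
absorbance in that channel) — the Beer–Lambert law. Writing the three unit
absorbance vectors as the rows of a matrix `M` (rows = hematoxylin, eosin,
DAB; columns = R, G, B; each row normalized to Euclidean length 1), a pixel
with stain amounts `c` (a row vector) produces the OD row vector
`y = c M`, and the amounts are recovered by colour deconvolution:

```
c = y M⁻¹ = y D ,   D = M⁻¹ .
```

`nucseg` assumes 8-bit input (`I0 = 255` per channel) and the widely used
reference H&E-DAB absorbance vectors `H = (0.650, 0.704, 0.286)`,
`E = (0.072, 0.990, 0.105)`, `DAB = (0.268, 0.570, 0.776)`, both
user-overridable. The diagonal of `D` for these vectors is
`(1.88, 1.13, 1.57)` to two decimals; note that published deconvolution
matrices sometimes appear in the transposed orientation (the diagonal is
the same either way), so `nucseg` fixes rows-as-stains throughout and
documents every array's orientation.

Nuclei bind hematoxylin, so the hematoxylin amount map (min-max rescaled to
[0, 1]; a constant map rescales to 0) is the working grayscale surface for
every later stage.

### Denoising

Acquisition noise is suppressed in two steps, in this order:

* **Gaussian smoothing**, kernel `exp(-(x²+y²)/2σ²)/(2πσ²)` discretized on
  `[-r, r]²` and renormalized to sum 1;
* **bilateral filtering**, the normalized product of a spatial Gaussian
  (`σ_s`) and a range Gaussian on intensity differences (`σ_r`), which
  smooths flat regions while keeping nucleus edges sharp for the watershed
  relief.

Both filters reflect the image at its borders (half-sample symmetric). That
choice matters twice: constant images are exact fixed points, and no
artificial dark frame appears at the border that would otherwise seed
spurious watershed basins. With `σ_r → ∞` the bilateral filter reduces
exactly to the Gaussian at `σ_s`, which the tests exploit as an oracle.

### Morphological reconstruction

Clutter smaller than a nucleus is removed with reconstruction operators
built from geodesic steps on a marker/mask image pair `(f, g)`:

* geodesic dilation `δ_g(f) = min(δ(f), g)` (requires `f ≤ g`),
* geodesic erosion `ε_g(f) = max(ε(f), g)` (requires `f ≥ g`), the
  standard dual,

each iterated until two successive iterates are identical. Opening by
reconstruction (`reconstruct-by-dilation of ε(f) under f`) removes bright
structures smaller than the structuring element but restores surviving
structures *exactly*, unlike a plain opening which rounds their corners;
closing by reconstruction is the dual for dark structures. The pipeline
applies opening then closing by reconstruction, then a plain closing at
half the radius to remove contour burrs.

The structuring element is a flat Euclidean disk (`dy² + dx² ≤ r²`); at
radius 1 this is the 4-neighbour cross. One consequence worth knowing: a
one-pixel notch on a *straight boundary* survives a disk closing of any
small radius (a 3×3 box would fill it), while an interior one-pixel pit is
filled at radius 1. Dilation and erosion at the image border use in-image
neighbours only (the −∞/+∞ padding convention).

### Markers: fast radial symmetry

Nuclei are approximately elliptical with near-circular outlines, so their
centres are found with the fast radial symmetry transform: every pixel
with gradient magnitude above a fraction of the image maximum casts a vote
`n` pixels along (bright polarity) or against (dark polarity) its gradient
direction; per radius, the vote-count image `O` (clamped at `k_n`, 8 for
`n = 1`, 9.9 otherwise) and gradient-magnitude sum `M` combine as
`(O/k_n)^α · M/k_n`, are smoothed with a Gaussian of `σ = 0.25 n`, and the
per-radius responses are averaged. Gradients come from 3×3 Sobel kernels.
The pipeline hands the transform the *inverted* prepared map with dark
polarity (nuclei are bright in the concentration map); a flag
(`frst.source`) selects the denoised rather than reconstructed map for
users who want markers before morphology.

Peak extraction is plain non-maximum suppression: 8-neighbourhood local
maxima at ≥ 30% of the global maximum, accepted greedily in descending
score order with an exclusion radius of one nucleus radius, ties broken by
(row, col). Accepted centres are stamped as small disks (radius 2 px),
labelled in order.

**Blank-field gate.** The transform and the peak threshold are both
relative to the image's own maxima, so a field containing *no* nuclei
would amplify noise into confident false centres. Marker detection is
therefore skipped when the prepared map's absolute hematoxylin contrast —
(range of the prepared map) × (range of the raw hematoxylin amounts), in
concentration units — falls below `markers.min_contrast` (default 0.1).
Typical nucleus/background contrast at realistic staining is ≈ 0.75;
noise-only fields measure ≈ 0.01. The gate is deliberately far from both.

### Watershed

The flooding relief is the morphological gradient (dilation − erosion,
disk radius 1) of the prepared map; an inverted-intensity surface is
available as a config option. Background markers come from Otsu's
threshold (computed over the data range, so the marker mask is invariant
to adding a constant), complemented and eroded by one nucleus radius.
Flooding is priority-queue (Meyer) propagation from all markers at once in
ascending (relief, row, col) order with 4-connectivity (8 optional);
pixels are labelled when first reached, so ridge pixels join the region
that gets there first and the whole pipeline is bit-deterministic.

## Parameters

| key | default | units | role |
|---|---|---|---|
| `gaussian.sigma` | 1.0 | px | noise scale of the first smoothing pass |
| `bilateral.sigma_spatial` | 2.0 | px | spatial support of edge-preserving pass |
| `bilateral.sigma_range` | 0.1 | [0,1] intensity | edge-contrast scale kept sharp |
| `*.radius` | `ceil(3σ)` | px | window truncation |
| `morphology.nucleus_radius` | 8 | px | expected nucleus radius; master scale |
| `morphology.se_radius` | `round(r/2)` | px | reconstruction disk |
| `frst.radii` | `{r−2, r, r+2}` | px | radii voted over |
| `frst.alpha` | 2 | — | radial strictness |
| `frst.gradient_threshold` | 0.05 | fraction | gradient votes ignored below |
| `markers.rel_threshold` | 0.3 | fraction | peak acceptance level |
| `markers.min_distance` | `r` | px | non-maximum suppression radius |
| `markers.min_contrast` | 0.1 | concentration | blank-field gate (above) |
| `watershed.connectivity` | 4 | — | flooding neighbourhood |

The defaults are sized for nuclei of 5–20 px radius: smoothing scales well
below the nucleus radius so no structure of interest is destroyed, the
reconstruction disk at half the nucleus radius removes sub-nuclear clutter
while every nucleus survives erosion, and the FRST radii bracket the
expected radius. Configuration is fail-closed: unknown keys are an error
with a nearest-key suggestion, so typos cannot silently fall back to
defaults.

## The synthetic generator

`generate_scene()` + `render_scene()` emulate a field of well-separated
H&E nuclei: a hard-core point process (pairwise centre distance ≥
`2 r_max + 2`, so nuclei never touch), elliptical nuclei with semi-major
axis uniform in 6–10 px and axis ratio in 0.7–1.0 (near-circular, mildly
anisotropic), rendered through the forward Beer–Lambert model with
hematoxylin/eosin amounts 0.8/0.1 inside nuclei and 0.05/0.35 in the
background — visually plausible H&E contrast — plus additive Gaussian
noise of σ = 3 on the 8-bit scale, strong enough to exercise the denoising
stages. All randomness flows from one integer seed and the caller's RNG
state is untouched. Rendered intensities stay continuous; quantization
only happens if an image is written to an 8-bit file, which keeps the
noise-free render → deconvolution round trip exact to 1e-6.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate — includes touching and overlapping nucleus clumps,
chromatin texture inside nuclei, stain variation across a slide, tissue
architecture, and out-of-focus blur. Scores on real tissue will be lower,
and splitting touching nuclei is explicitly limited to what distinct FRST
markers provide.

Test and validation problem sizes are 256×256 scenes with 30 nuclei (20
seeds for the end-to-end recovery checks) and 16×16/32×32 images for the
brute-force operator oracles; these sizes make every oracle exhaustively
checkable while the statistics remain stable.

## Numerical choices

* Intensities are clamped to ≥ 1 before the OD log, so an all-black pixel
  maps to a finite density (≈ 2.41) instead of ∞.
* Reconstruction stability is exact array equality, with an `H·W`
  iteration cap (the iteration is monotone and bounded, so the cap is a
  safety assertion, not a tolerance).
* Degenerate inputs are errors, not guesses: zero stain vectors, singular
  stain matrices (named), `σ ≤ 0`, marker/mask order violations (first
  offending pixel reported), overlapping foreground/background markers.
* Constant images: zero FRST response, empty background marker mask (with
  a warning), zero relief — a constant image segments to "no nuclei".
* Half-up rounding to one decimal for detection-rate percentages
  (`93/101 → 92.1`).
* Float TIFF stain maps are stored as `value/4` (exact power-of-two
  scaling into the writer's [0, 1] float range, values clipped to [0, 4]);
  `read_stain_map()` undoes the scaling.

## Known limitations

* One marker, one region: a missed centre merges a nucleus into the
  background; a double detection splits one nucleus in two. The count
  recovery of the pipeline is only as good as the FRST stage.
* The stain matrix is fixed per run; there is no per-slide stain
  estimation or normalization.
* The direct bilateral filter is `O(N·w²)`; at desk-scale images
  (≤ 1024²) this is seconds, but whole-slide tiles would want an
  approximate method.
* Labels are written as 16-bit TIFF, capping a single field at 65 535
  nuclei.
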