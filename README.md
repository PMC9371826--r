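# nucseg

Marker-controlled watershed segmentation of cell nuclei in H&E-stained
microscopy images.

## The problem

Quantitative analysis of hematoxylin-eosin (H&E) histology starts from the
individual cell nucleus, and the classical watershed transform — flooding the
image's gradient relief from its regional minima — oversegments badly on real
tissue: every noise dimple becomes a basin. The standard remedy, implemented
here, is to decide *first* where the nuclei are and let each detected nucleus
seed exactly one watershed basin.

The pipeline:

1. **Stain separation.** Per channel, the optical density
   `OD_c = -log10(I_c / I0_c)` is additive across stains and linear in stain
   amount (Beer–Lambert). With the unit-normalized stain matrix `M`
   (rows = hematoxylin, eosin, DAB over R,G,B) and `D = M⁻¹`, the per-pixel
   stain contributions are recovered by `C = y D` from the OD vector `y`.
   For the standard H&E-DAB vectors the diagonal of the deconvolution matrix
   is `(1.88, 1.13, 1.57)`. The hematoxylin map (nuclei bright) is the
   working surface from here on.
2. **Denoising.** Gaussian smoothing (`σ = 1 px`) followed by an
   edge-preserving bilateral filter (`σ_s = 2 px`, `σ_r = 0.1` on the
   [0,1] intensity scale).
3. **Morphological reconstruction.** Opening by reconstruction then closing
   by reconstruction with a flat disk (radius = half the expected nucleus
   radius) flatten clutter smaller than a nucleus without deforming the
   nuclei; a half-size plain closing smooths residual contour burrs.
4. **Markers.** The fast radial symmetry transform (gradient voting at the
   expected radii) peaks at nucleus centres; local maxima above 30% of the
   global peak, with non-maximum suppression at one nucleus radius, become
   foreground markers. Otsu thresholding, complemented and eroded, gives the
   background marker.
5. **Watershed.** Priority flooding of the morphological gradient from all
   markers at once; each marker grows into exactly one labelled region, so
   the nucleus count equals the marker count by construction.

Everything is deterministic: ties in flooding and peak extraction break by
(value, row, col).

## Worked example

The package ships a seeded synthetic-scene generator with exact ground
truth, so the whole pipeline can be exercised without any data download:

```r
library(nucseg)

scene <- generate_scene(n_nuclei = 30, size = 256, seed = 7)
truth <- render_scene(scene)          # forward Beer-Lambert render + noise
seg   <- segment_nuclei(truth$image)  # the full pipeline, default config
seg
#> nucseg segmentation: 256 x 256 image, 30 nuclei

head(seg$centers, 3)
#>    row col     score
#> 10  31 201 0.5556156
#> 18  39  28 0.5175729
#> 24  43 144 0.3853825

metrics <- evaluate_segmentation(seg$labels, seg$centers,
                                 truth$labels, truth$centers, max_dist = 8)
str(metrics[c("precision", "recall", "f1", "mean_dice")])
#> List of 4
#>  $ precision: num 1
#>  $ recall   : num 1
#>  $ f1       : num 1
#>  $ mean_dice: num 0.998
```

All 30 nuclei are found (F1 = 1) and the matched watershed regions overlap
the true elliptical masks with a mean Dice of 0.998. The stain arithmetic
can be checked directly:

```r
round(diag(deconvolution_matrix(normalize_stain_vectors(he_dab_stain_matrix()))), 2)
#> [1] 1.88 1.13 1.57
detection_rate(93, 101)   # modality worked example: 93 lesions in 101 patients
#> [1] 92.1
```

## Command line

`inst/cli/nucseg` wraps the same functions:

```sh
nucseg synth --n 30 --size 256 --seed 7 --out-image img.png \
       --out-labels gt.tif --out-centers gt.csv
nucseg segment img.png --out-labels pred.tif --out-centers pred.csv
nucseg evaluate --pred pred.tif --truth gt.tif \
       --pred-centers pred.csv --truth-centers gt.csv --max-dist 8
```

Labels are 16-bit TIFF; centre CSVs use 0-based (row, col) coordinates;
every run writes a JSON run report (config snapshot, stage timings, paths,
version, seed).

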