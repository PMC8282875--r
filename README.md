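# msmseg

Automatic segmentation and classification of skin cells in label-free
multiphoton microscopy slices.

## The problem

In vivo multiphoton tomography records two-photon-excited autofluorescence
(TPEF) of the epidermis as 8-bit photon-count slices (typically 512 × 512 px
at 0.39 µm/px). NAD(P)H-rich mitochondria make the cell cytoplasm bright and
speckled, cell nuclei are dark and near-circular, and the intercellular
matrix is dark and granular. Contrast is low, falls off toward the image
edges, and cells shrink with imaging depth, so pipelines built around a
single global threshold fail. `msmseg` is for image-analysis researchers and
microscopists who need a fully automatic, threshold-ladder-based
nucleus/cytoplasm/matrix segmentation of such data, plus a synthetic phantom
generator and an object-level evaluation protocol to validate it without
patient data.

## The method

1. **Pre-processing.** Plateau transform `I_TH = I + T_w(I) + T_b(I)` with
   white/black top-hats over an 11-px circular structuring element, CLAHE
   (16-px tiles, clipped histograms, bilinear tile interpolation), and
   Perona–Malik anisotropic diffusion with coefficient
   `d(∇) = 1 / (1 + (∇/K)²)` over the 8-neighbourhood.
2. **Over-segmentation.** Watershed flooding of the Gaussian-smoothed Sobel
   gradient magnitude `G = √(D_x² + D_y²)`; basins become superpixels
   summarized by their mean intensity.
3. **Multi-stage merging.** A flooding merge joins adjacent regions whose
   mean-intensity difference is ≤ `T_m`, run independently for
   `T_m = 70, 60, …, 10`; stages are combined so high-contrast objects are
   locked in first and new object area is admitted only on the remaining
   background. A per-pixel **stability index** `S` counts the stages in
   which a region persists as foreground.
4. **Semantic assignment.** An enclosure hierarchy of nested contours feeds
   the outer-cell/inner-nucleus (OCIN) sign rule
   (`Σ (I_inner − I_outer) < 0` ⇒ nucleus); each nucleus candidate gets a
   quality score — the Euclidean distance of its normalized feature vector
   (stability `S`, contour gradient `|∇I|`, compactness `C = P²/(4πA)`,
   OCIN hierarchy index `H`) from the ideal nucleus model — and the
   scene-relative threshold `d < (max d − min d)(1 − T_qual) + min d`
   (default `T_qual = 0.97`) selects the final nuclei. Adjacent cell
   candidates become cytoplasm; everything else is matrix.

## Worked example

```r
library(msmseg)

spec <- phantom_spec(shape_px = c(256L, 256L), n_cells = 6L,
                     cell_radius_px = c(22, 30), speckle_strength = 0,
                     open_boundary_fraction = 0, seed = 42L)
ph  <- generate_phantom(spec)
res <- run_slice(ph$image, msm_config())
#> pipeline: 887 superpixels -> 29 segments -> 6 candidates -> 2 nuclei (1.4s)

head(res$features[order(res$features$d),
     c("label", "area", "S", "grad", "C", "H", "d", "selected")], 7)
#>   label area S grad     C H     d selected
#> 3    12  541 5 36.9 0.995 1 0.902     TRUE
#> 1     8  447 5 36.5 1.008 1 0.903     TRUE
#> 2    10  444 5 35.1 0.979 1 0.909    FALSE
#> 4    16  501 5 35.1 0.978 1 0.909    FALSE
#> 5    22  432 4 38.5 0.997 1 0.951    FALSE
#> 6    23  339 4 32.2 0.984 1 0.973    FALSE

pred <- matrix(res$msr$final_labels %in% res$sem$selected, 256)
dice(pred, ph$gt$nucleus_labels > 0)
#> [1] 0.508

threshold_sweep(res$features, res$msr$final_labels, ph$gt)$best_threshold
#> [1] 0.9
```

Reading the numbers: the watershed produces 887 superpixels which the
threshold ladder fuses into 29 segments; all 6 ground-truth nuclei come out
as candidates with hierarchy index `H = 1` (canonically enclosed by their
cytoplasm), compactness ≈ 1 (circular), and stability 4–5 of a possible 6.
The scene-relative default threshold 0.97 keeps only the candidates within
3% of the scene's quality range and therefore selects 2 of the 6 —
which is why the sweep finds the lower threshold 0.900 optimal for this
clean scene (there it selects all six and the Dice coefficient rises
accordingly).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/msmseg.R", package = "msmseg"))')
Rscript "$CLI" phantom --out fixtures --seed 3
Rscript "$CLI" run    --input fixtures/phantom.tif --out results_run
Rscript "$CLI" sweep  --input fixtures/phantom.tif --gt-nuclei fixtures/gt_nuclei.tif \
                      --certainty fixtures/certainty.csv --out results_sweep
Rscript "$CLI" noise  --input fixtures/phantom.tif --gt-nuclei fixtures/gt_nuclei.tif \
                      --sigmas 0,5,10 --seeds 1,2,3 --out noise.csv
```

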