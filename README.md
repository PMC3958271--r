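# veinfuse

Finger-vein image enhancement by fuzzy fusion of Gabor and Retinex
filtering, with the full verification chain needed to measure it.

Near-infrared transillumination shows subcutaneous finger veins as dark
curvilinear tracks on brighter skin (deoxyhemoglobin absorbs 760–850 nm
light), but skin scattering, optical blur and uneven illumination leave the
pattern low-contrast and noisy. `veinfuse` enhances such images by running
two complementary filters and fusing them pixel by pixel:

* a **four-directional even-symmetric Gabor bank** — kernels
  `G_θ(x,y) = (2πσ_xσ_y)⁻¹ exp(−½(x_θ²/σ_x² + y_θ²/σ_y²)) cos(2πf x_θ)`
  at θ = iπ/4 (f = 0.05 cycles/px, σ = 9.53), combined by the per-pixel
  **minimum** across orientations, which selects the channel best aligned
  with the (dark) vein at each position — amplifies local, oriented
  vein-line structure;
* **single-scale Retinex** — `log r = log(L+ε) − log(G_σ∗L+ε)` with a
  unit-sum Gaussian surround (σ = 20 by default) — normalizes illumination
  and raises global vein/skin contrast.

The fusion weight `w` at every pixel comes from a 16-rule Mamdani fuzzy
system on the min-max-normalized local window means and standard deviations
of the two filtered images (window 21 px): low mean + high STD means "vein
under the window" and pushes weight toward the image that shows it better.
Inference uses the Min or Max rule; defuzzification offers FOM, LOM, MOM,
MeOM and an exact-centroid COG. The fused pixel is
`V_O = w·V_G + (1−w)·V_R`.

Downstream, the package implements finger-region detection by 20×4 edge
templates, size normalization to 150×60 and 3×3 block-mean downsampling to
50×20, 6,912-bit LBP vein codes matched by normalized Hamming distance,
128 wavelet-packet features (3-level full packet tree, Haar or db2) matched
by RMS Euclidean distance, all-pairs FAR/FRR/EER evaluation, and a seeded
synthetic NIR vein-image generator with ground-truth masks so everything is
testable without any database.

## Worked example

```r
library(veinfuse)

# one synthetic 320x240 NIR frame with ground truth
li <- generateImage(syntheticSpec(seed = 7), classId = 1, sampleId = 1)
li
#> LabeledVeinImage: class 1 sample 1, 240 x 320, 14.0% vein

# full enhancement chain: boundaries -> crop -> Gabor -> Retinex -> fusion
e <- enhanceImage(li@image)        # default: Min rule + LOM, Retinex sigma 20
dim(e$enhanced)
#> [1] 122 300
summary(as.numeric(e$weights))     # per-pixel Gabor weight map
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.2298  0.6025  0.6860  0.6641  0.7324  1.0000

# LBP vein code and matching
code <- extractFeatures(e$enhanced, e$roi, "lbp")
code
#> VeinCode: 6912 bits (8 x 48 x 18), density 0.514
```

A second sample of the same finger gives a Hamming distance of `0.264`; a
different finger gives `0.539` — genuine pairs are far closer than
imposters, which is what the verification stage quantifies:

```r
g <- generateGallery(syntheticSpec(seed = 7), classes = 5, perClass = 3)
res <- evaluateGallery(g)          # all-pairs matching
res$pairs
#> authentic  imposter
#>        15        90
res$eer
#> EERResult: EER = 0.0000% at threshold 0.354167 (104 ROC points)
```

The EER is the error rate at the threshold where the false acceptance rate
(fraction of imposter distances accepted) is closest to the false rejection
rate (fraction of genuine distances rejected); 0% means the two score
populations separate completely on this small clean gallery.

The fuzzy stage itself can be inspected directly; with the four normalized
inputs 0.61, 0.45, 0.33, 0.73 the 16 inference pairs are:

```r
inferenceGrid()[1:3, c("pair","f1","f2","f3","f4","minIV","maxIV","label")]
#>   pair   f1   f2   f3   f4 minIV maxIV label
#> 1    1 0.39 0.55 0.67 0.27  0.27  0.67     M
#> 2    2 0.39 0.55 0.67 0.73  0.39  0.73     L
#> 3    3 0.39 0.55 0.33 0.27  0.27  0.55     M
```

A thin command-line front end with `simulate`, `enhance`, `features`,
`evaluate` and `reproduce-table3` subcommands is installed at
`inst/scripts/veinfuse-cli.R`.

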