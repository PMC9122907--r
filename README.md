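# fazseg

Lightweight attention U-Nets for segmenting the foveal avascular zone (FAZ)
in en-face OCT-angiography images, plus the complete downstream morphometry
and statistics pipeline.

The FAZ — the capillary-free region at the centre of the retina — is a
candidate biomarker for glaucoma and other diseases: its area (mm²),
perimeter (mm) and circularity index change with disease. Measuring it
automatically requires pixel-accurate segmentation of images that are
routinely degraded by salt-and-pepper noise, horizontal scan lines,
capillary dropout and blur. `fazseg` is aimed at researchers who want a
self-contained, fully seeded implementation of that pipeline in R: the
network family, the training protocol, the contour-based morphometry, the
agreement/discrimination statistics, and a synthetic image generator with
analytic ground truth so everything is testable without clinical data.

## The model family

Seven encoder–decoder presets share a four-level backbone (two 3×3
conv + batch-norm + ReLU blocks per level, 2×2 max-pooling, dropout after
every pooling/upsampling step) and differ in width policy (doubling from 64
vs fixed 128/64 channels), skip merging (concatenation vs addition),
upsampling (learned 3×3 stride-2 transposed convolution vs parameter-free
nearest-neighbour), and channel attention. The attention block is a
modified squeeze-and-excitation unit — global average pooling, one dense
C→C layer, then ReLU *followed by* a logistic squashing — which bounds
every channel weight to [0.5, 1): weak channels are halved, never
eliminated.

The flagship `LWBNA_Unet` adds bottleneck channel narrowing with attention:
successive convolutions squeeze the 128-channel bottleneck down
128 → 64 → 32 → 16 (attention after each step), restore to 128, add a skip
from the midblock input, and apply a final attention block. Only features
needed to reconstruct the segmentation pass the waist, which suppresses
spurious FAZ-like detections in noisy images at ~1/10 of the baseline
U-Net's parameters:

| preset                        | parameters |
|------------------------------|-----------:|
| Unet                          | 28,340,931 |
| Unet_AB                       | 29,830,275 |
| Unet_AB_Upsampling            | 24,466,627 |
| Unet_AB_Upsampling_Add        | 12,259,523 |
| Unet_AB_128_Upsampling_Add    |  2,673,795 |
| Unet_AB_64_Upsampling_Add     |    673,347 |
| LWBNA_Unet                    |  2,958,819 |

Counts include batch-normalisation moving statistics (Keras "total
parameters" convention). The convolutional engine (forward, backprop, Adam,
attention, batch norm) is single-precision C++ via Rcpp/RcppArmadillo; all
randomness is explicitly seeded, so training runs are bit-reproducible on
one machine.

Morphometry follows the standard contour pipeline: threshold at 0.5, label
8-connected regions, trace each region's outer boundary, keep the largest
contour, then compute area (shoelace with half-boundary correction),
perimeter (smoothed closed polyline) and circularity CI = 4πA/P².

## Worked example

Train the lightweight preset on synthetic OCTA-like images and measure the
FAZ on a held-out image (a few minutes on a laptop CPU):

```r
library(fazseg)

cfg <- synth_config_clear(synth_config(image_size = c(96, 96),
                                       radius_range = c(8, 20),
                                       center_jitter = 5,
                                       vessel_density = 30))
ds  <- make_dataset(100, cfg, base_seed = 100)
arr <- dataset_arrays(ds)

model <- build_model("LWBNA_Unet", input_size = c(96, 96), seed = 1)
fit <- train_model(model,
                   arr$x[, , , 1:60],  arr$y[, , 1:60],
                   arr$x[, , , 61:80], arr$y[, , 61:80],
                   train_config(learning_rate = 1e-3, max_epochs = 15,
                                early_stopping = FALSE, seed = 1),
                   verbose = TRUE)
#> epoch   3  loss 0.0438  val_loss 0.0734  val_D 0.9610
#> ...
#> epoch  15  loss 0.0143  val_loss 0.0140  val_D 0.9888

evaluate_testset(fit$model, arr$x[, , , 81:100], arr$y[, , 81:100])
#> <faz_eval> 20 images
#>   mean D (raw)     0.9894  (sd 0.0035)
#>   mean D (largest) 0.9894  (sd 0.0035)
#>   images with >1 region: 0; extra contours: 0

analyze_image(fit$model, ds$samples[[81]]$image)
#> <faz_measurement> A = 0.4382 mm^2, P = 2.268 mm, CI = 1.070 (1 region)
```

(The analytic truth for that sample is 0.4517 mm². The Dice coefficient D
compares predicted and true masks, 1 = identical; the "largest contour"
Dice keeps only the biggest segmented region, which removes small spurious
detections. Circularity can slightly exceed 1 for near-circular regions a
few pixels across — a discretisation effect documented in the vignette.) Comparing measured against analytically
true areas on the 20 test images gives a Bland–Altman bias of
−0.0046 mm² — about 0.7% of the mean true area.

A thin command-line front-end covers the same pipeline
(`simulate | train | predict | analyze | agree | roc`):

```sh
Rscript inst/cli/fazseg.R simulate --n 20 --seed 1 --size 96 --out data/
Rscript inst/cli/fazseg.R analyze --masks data/ --scale-mm 3 --out faz.csv
```

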