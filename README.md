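# cmfd — copy-move forgery detection for medical images

Copy-move forgery duplicates a region of an image and pastes it elsewhere in
the same image — in medical imaging, typically to hide or fabricate a
finding. `cmfd` implements a three-stage detector for this tampering class,
aimed at image-forensics practitioners and method researchers who need a
reproducible, scriptable pipeline with pixel- and image-level evaluation:

1. **SIFT keypoint seeding.** The image is converted to grayscale with the
   weighted sum `0.299 R + 0.583 G + 0.116 B` and standard SIFT keypoints
   (difference-of-Gaussians extrema with 128-d descriptors) are detected.
   No descriptor matching is performed — keypoints act purely as suspicion
   seeds for the block stage.
2. **Equilibrium-optimizer block matching.** The image is decomposed into
   all one-pixel-stride overlapping `B x B` blocks (`(H-B+1)(W-B+1)` of
   them; `B = 8`). Keypoint-bearing blocks form a particle population whose
   "concentrations" are the blocks' pixel windows. Per iteration, each
   block's fitness is the mean squared difference between its standard
   deviation and those of the whole population,
   `f(u) = mean_i (STD(u) - STD(i))^2`; the four best blocks plus their
   average form the equilibrium pool; each concentration is then updated by
   `C' = C_eq1 + (C_eq1 - C) F + (G / lambda)(1 - F)` with the exponential
   term `F = a1 sign(r - 0.5) e^(-lambda STD) - a2` (`a1 = 2`, `a2 = 1`) and
   generation rate `G = GCP (C_eq1 - lambda C) F`, `GCP = 0.5 r1` when
   `r2 >= GP = 0.5`, else 0. Blocks whose updated concentration qualifies
   for the pool are re-weighted toward white (`window <- STD(C') * window`),
   the rest toward black (`window <- STD(C')/100 * window`); thresholding
   the re-weighted image at 127.5 yields the suspicion map.
3. **Color-histogram region growing and closing.** Suspected blocks are
   expanded through their 8-connected block neighborhood by Euclidean
   distance between L1-normalized per-channel color histograms, and the
   mask is finished with a morphological closing by a disk of radius 5.

The package also provides the evaluation metrics (precision, recall, F1,
sensitivity, specificity at pixel and image level, with per-category report
tables) and a synthetic forgery generator — plain, rotated (5/10/15 degree)
and Gaussian-noise (sigma 0.1) copy-move forgeries over procedurally
generated soft-tissue-like images, each with an exact ground-truth mask —
so the whole pipeline is testable without any external data.

## Worked example

```r
library(cmfd)

base   <- generate_base_image(seed = 42, H = 256, W = 256)
les    <- attr(base, "lesion")                       # the feature-rich window
forged <- apply_copy_move(base,
            forgery_spec(les$origin, les$size, dest_origin = c(30, 150)))

det <- detect_forgery(forged$image, run_config(seed = 42))
det
#> cmfd_detection: verdict forged; 111 keypoints, 3080 candidate blocks, 4809 mask pixels

detection_scores(confusion_counts(det$mask, forged$mask))
#> detection_report: A1=4366 B1=242 A2=60485 B2=443
#>   precision 90.79  recall 94.75  F1 92.73  sensitivity 94.75  specificity 99.27
```

The verdict says a connected mask component of at least one block (64
pixels) was found; the confusion counts compare the predicted mask with the
ground truth pixel by pixel: here 94.75% of the truly duplicated pixels are
recovered (recall/sensitivity) and 90.79% of flagged pixels are truly
duplicated (precision), for a pixel-level F1 of 92.73%.

A command-line interface wraps the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cmfd.R", package = "cmfd"))')" \
    generate --out data --n 2 --seed 1
Rscript .../cmfd.R detect --image data/simple_001.png --out pred.png
Rscript .../cmfd.R evaluate --manifest data/manifest.csv --predictions preds/
```

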