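---
title: "Copy-move forgery detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-move forgery detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science behind `cmfd`: the detection model and
its assumptions, every tunable parameter with its default and rationale,
what the synthetic data emulate (and what they do not), the numerical and
design choices made where the method's description left the design open,
and the known limitations. It states no empirical result that the package's
tests and `scripts/acceptance.R` do not themselves compute.

## The detection model

Copy-move forgery duplicates part of an image inside the same image. The
detector combines a keypoint stage (good at finding feature-rich,
potentially duplicated structure cheaply) with a block stage (good at dense
localization), followed by a region-growing cleanup:

1. **Grayscale conversion.** `GrayImage = 0.299 R + 0.583 G + 0.116 B`.
   These weights are the detector's native convention; they differ slightly
   from ITU-R BT.601 (0.299, 0.587, 0.114), whose weights are available via
   `to_gray(variant = "bt601")`. We default to the native weights for
   fidelity to the method and keep grayscale values real-valued internally:
   quantizing to integers before computing block standard deviations would
   compound rounding into the fitness function.

2. **SIFT seeding.** Standard SIFT (DoG extrema, 128-d descriptors;
   contrast threshold 0.04, edge threshold 10 — the classical defaults)
   provides *suspicion seeds only*. Unlike most keypoint detectors of this
   family, no g2NN descriptor matching is performed; the block stage does
   the matching. Keypoints are binned into the integer pixel they fall in
   (floor convention, 0-based), deduplicated per pixel, and every `B x B`
   block covering a keypoint pixel becomes a *candidate block* — so a block
   holds at most `B^2 = 64` keypoints.

3. **Equilibrium-optimizer matching.** Candidate blocks are particles whose
   "concentration" is the block's pixel window. The fitness of a block is
   the mean squared difference between its standard deviation (population
   SD, divisor `B^2`) and those of all candidates. The four lowest-fitness
   blocks plus their element-wise average form the equilibrium pool. Each
   iteration re-reads every candidate window from the working image, draws
   `lambda, r, r1, r2 ~ U[0,1]` per candidate (in that fixed order from one
   seeded stream), forms the exponential term
   `F = a1 sign(r-0.5) exp(-lambda STD) - a2`, the generation rate
   `G = GCP (C_eq1 - lambda C) F` with `GCP = 0.5 r1 [r2 >= GP]`, updates
   `C' = C_eq1 + (C_eq1 - C) F + (G / lambda)(1 - F)`, and re-weights the
   block's window in place: members of the equilibrium pool are multiplied
   by `STD(C')` ("convert to white"), non-members by `STD(C')/100`
   ("convert to black"), clipped to `[0, 255]`. After `max_iter` iterations
   the working image is thresholded at 127.5: bright pixels are suspected.

4. **Histogram region growing + closing.** Blocks at least half covered by
   suspected pixels seed a breadth-first expansion over the 8-connected
   block lattice (neighbors one block-step away at the eight compass
   angles). A frontier block annexes its minimum-distance neighbor if the
   Euclidean distance between their L1-normalized 32-bin-per-channel color
   histograms is at most `distance_threshold`. Seeds are processed in
   descending keypoint count — the deterministic reading of "blocks with
   more keypoints are more likely to be expanded". A morphological closing
   with a disk of radius 5 (dilation then erosion, computed on a padded
   canvas so it matches unbounded-plane closing and is extensive and
   idempotent) fills the remaining gaps.

An image whose mask contains an 8-connected component of at least
`min_region_pixels = 64` pixels (one full block) is declared forged.

## Parameters

| key | default | meaning / rationale |
|---|---|---|
| `block_size` | 8 | block side in pixels; fixed by the method |
| `a1`, `a2`, `gp` | 2, 1, 0.5 | equilibrium-optimizer constants; fixed by the method |
| `max_iter` | 20 | matcher iterations; the white/black partition forms in the first pass and remains quasi-stable afterwards (see below), so results are insensitive to this value |
| `lambda_floor` | 1e-6 | guard before dividing by `lambda ~ U[0,1]` in the update |
| `threshold` | 127.5 | white/black binarization midpoint of the 8-bit range |
| `f_variant` | `"printed"` | exponential term as stated above; `"canonical"` gives the classical form `a1 sign(r-0.5)(exp(-lambda STD) - 1)` |
| `member_rule` | `"mean"` | pool-membership cutoff (see design notes) |
| `contrast_threshold`, `edge_threshold` | 0.04, 10 | classical SIFT defaults; the contrast value is divided by the 3 scales per octave, the usual convention |
| `sift_max_scale` | 8 | keypoints detected at scales coarser than a block mark whole-organ blobs, not block-level detail, and are excluded from seeding (see design notes) |
| `n_bins` | 32 | histogram bins per channel |
| `distance_threshold` | 0.1 | annexation cutoff on L1-normalized histograms; conservative (see design notes) |
| `max_rounds` | 50 | frontier passes; guarantees termination |
| `closing_radius` | 5 | disk radius of the closing; fixed by the method |
| `min_region_pixels` | 64 | image-level verdict: smallest forged component, one full block |
| `noise_sigma` | 0.1 | noise level of the synthetic noise category, on `[0,1]` intensities |
| `seed` | 1 | one RNG stream for the whole run; identical inputs and seed give bit-identical masks |

## Design decisions where the method description was open

**Pool membership (`member_rule`).** The re-weighting step needs a test
"is the updated concentration in the equilibrium pool?", which is undefined
for a freshly updated, real-valued concentration. Two readings are
implemented. `"pool"` admits an update whose fitness is no worse than the
pool's fourth member. With realistic candidate populations (hundreds to
thousands of blocks) this cutoff is the fourth order statistic of the
fitness distribution: only ~4 blocks qualify per pass, and because
candidate windows overlap up to 64-fold, the sequential multiplicative
darkening of all other blocks erases the few whitened windows — the
white/black partition the method is built on never forms (the package's
matcher tests exercise this regime). `"mean"`, the default, admits an
update whose fitness is no worse than the population's *average* fitness —
"at least as well-balanced as a typical particle". Under it, blocks whose
texture statistics sit near the population's center whiten, outliers
darken, and the partition forms in one pass and remains quasi-stable under
further iterations (partially whitened windows have high variance and keep
re-whitening; fully flat ones are occasionally erased and re-whitened by
overlapping neighbors). Both rules share every other equation.

**Keypoint scale filter.** SIFT on smooth anatomy returns a few keypoints
at very coarse scales (sigma of tens of pixels) centered on organ-sized
blobs. Binning a sigma-40 detection into a single 8x8 block would seed a
false suspicion cluster bearing no block-level evidence, so the pipeline
keeps only keypoints with `scale <= block_size`. The detector itself
(`detect_sift`) is unfiltered; the filter is a pipeline policy
(`filter_keypoints`).

**Histogram expansion is conservative by default.** On the synthetic
fixtures, the Euclidean distance between 64-pixel block histograms carries
little contrast between "same duplicated region" and "adjacent background"
neighbors (both distributions overlap heavily; the package's expansion
tests compare against an independent BFS oracle instead of asserting
discrimination). The default `distance_threshold = 0.1` therefore keeps
expansion a minor, precision-preserving step; localization rests mainly on
the matcher's suspicion map plus the closing. Users with imagery whose
color statistics genuinely separate regions can raise the threshold.

**Other pinned conventions.** Population (not sample) standard deviation,
so constant blocks give exactly 0 regardless of `B`; 0-based, row-major
block coordinates with half-open windows; fitness ties in pool selection
broken by row-major block order; `r2 = GP` takes the `0.5 r1` branch;
within an iteration, fitness, the pool and all updates are computed from
the iteration-start snapshot while re-weighting mutates the working image
in candidate order (re-reading mutated windows mid-iteration would make the
result depend on processing order twice over). Images with fewer than four
candidates short-circuit to an all-authentic map, since the pool needs four
members.

## The synthetic data: what they emulate, and what they do not

`generate_base_image` emulates a soft-tissue scan: 4-6 overlapping
soft-edged ellipses on a dark background (intensities capped at ~124, the
dark side of the 8-bit range), weak band-limited texture everywhere, and
one feature-rich "lesion": Gaussian speckle (smoothing sigma 0.9, amplitude
45) filling a soft-edged square aligned with the copy window, its plateau
rolling off a few pixels inside the window edge. The alignment encodes the
assumption that a forger copies a window from within distinctive structure;
the interior rolloff keeps SIFT detections a few pixels inside the window,
as real lesion texture fades into its surroundings. `apply_copy_move`
pastes the (optionally rotated, bilinear-interpolated) window at a disjoint
destination; the mask marks both members of the duplicated pair, with
rotated-paste membership decided by majority coverage of the rotated
indicator. The noise category adds global zero-mean Gaussian noise with
sigma 0.1 on unit-scaled intensities — "global" being the harder case for a
detector, since it perturbs both copies independently.

What passing tests on these fixtures show: the pipeline localizes exact and
small-rotation duplications of feature-rich regions on dark-background
imagery, deterministically per seed. What they do not show: performance on
real scanner noise, compression artifacts, bright-background modalities
(see limitations), duplications of *smooth* regions (which produce no
keypoints and are invisible to this detector by construction), or forgeries
whose surroundings are as feature-dense as the copied region itself.

Problem sizes were chosen to keep the whole suite desk-scale: detection
fixtures are 256x256 with a 48x48 duplicated window (ten plain and ten
rotated per run), unit-test fixtures 64-160 pixels.

## Numerical choices

Block standard deviations are computed two-pass (mean, then mean squared
deviation) in vectorized chunks rather than via the
`E[x^2] - E[x]^2` identity, which loses up to half the significand to
cancellation on low-variance blocks; the unit tests pin agreement with a
brute-force oracle at 1e-9 relative. Grayscale stays floating point until
file export. The closing pads by the disk radius before dilating so border
regions close exactly as in the unbounded plane. Mask PNGs encode {0, 255}
and round-trip bit-exactly.

## Known limitations

- The matcher has no pairwise verification: it whitens blocks whose
  *statistics* are typical of the candidate population, so an authentic
  image containing one feature-rich region is also flagged. Image-level
  specificity on authentic-but-textured images is accordingly poor; the
  method's strength is localization on images known to be suspect.
- The binarization threshold (127.5) assumes the working image's untouched
  background stays below mid-gray. On bright-background modalities the
  threshold, or the input windowing, must be adapted.
- Only PNG, TIFF and JPEG inputs are supported (no BMP or DICOM readers in
  the R stack used); convert such inputs first.
- Robustness degrades with rotation angle and added noise; the synthetic
  categories exist precisely to measure that degradation.
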