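---
title: "Methods: sparse-to-dense DNA-PAINT reconstruction with upaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-to-dense DNA-PAINT reconstruction with upaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

DNA-PAINT acquires a super-resolution image by localizing stochastic,
transient binding events over tens of thousands of camera frames — typically
close to an hour of acquisition for one field of microtubules. Most of that
time is spent densifying an image whose structures are already sketched out
after a few minutes. `upaint` shortens acquisition by treating densification
as an image-to-image regression problem: a U-Net learns to map a *sparse*
localization render (built from a small number of frames, *n*), optionally
paired with a diffraction-limited *widefield* image of the same field, to the
*dense* render that the full acquisition (*N* frames, *N* >> *n*) would have
produced.

The package covers the whole workflow in R: a microtubule simulator that
manufactures training data, readers/filters/renderers for single-molecule
localization tables, tiling and normalization into training triplets, the
network itself with its training loop, and the evaluation protocol
(RMSE, PSNR, SSIM on a [0, 255] scale, with two-sample model comparison).

## The microtubule simulator

Real training data is expensive, so simulated filaments supplement it.
Each simulated field is a random walk:

* `n_trajectories` (default 10) filaments start at uniformly random points
  on the boundary of a `field_width` (default 512 px) square.
* At every one of `n_frames` (default 500) frames each filament advances by
  exactly `step_length` = 0.5 px. The heading is the direction toward the
  field center, perturbed by a normal angle with `heading_noise_sd`
  (default 0.35 rad). This construction keeps the step length exactly fixed
  while making the *displacement* between nearby positions normally
  distributed around the toward-center direction; the half-pixel step keeps
  trajectories continuous and smooth, and 500 frames suffice for most
  filaments to cross the field.
* The **dense ground truth** overlays all frames into a count image (floor
  binning: pixel *(i, j)* covers *[i, i+1) × [j, j+1)*), blurs with a
  Gaussian of σ = 1.25 px, and center-crops to `tile_size` (default 256).
* The **widefield** channel blurs the ground-truth tile with σ = 20 px,
  area-averages down to a 32-px grid (the integration a diffraction-limited
  camera performs) and scales back up bilinearly — its spatial frequency
  content is limited accordingly.
* The **sparse** channel selects 10% of the frames uniformly at random
  (`round`-half-up count) and applies the identical overlay/blur/crop chain.

Choices the procedure leaves open, decided here once and exposed as
configuration: the heading-noise standard deviation (0.35 rad gives gently
curving, realistically wavy filaments; 0 gives straight rays), the rescale
factor between the working grid and the render (1:1 with a center crop,
the simplest chain under which filaments span the image), reflective
padding for all Gaussian blurs (avoids dark rims on cropped tiles; a
constant field stays constant), and area-average down / bilinear up for the
widefield resizes.

Normalization of a simulated triplet: sparse and dense renders share the
dense maximum as divisor, preserving the physical fact that a 10% frame
subset carries about 10% of the intensity; the widefield channel is
normalized to its own maximum. (Real-data preparation instead normalizes
every channel to its *own* uncut maximum — see below — because sparse and
dense acquisitions there are rendered independently.)

What the simulator does **not** emulate: microtubules are hollow ~26 nm
cylinders, so real filaments are thicker than these 1-point-wide paths;
there is no blinking kinetics, photon-count noise, camera noise, or 3-D
structure. Tests passing on simulated data therefore demonstrate the
pipeline's correctness and the network's capacity to densify sparse
structure, not performance on real acquisitions.

## Localization tables and rendering

The package consumes already-fitted localization tables (Picasso-style
HDF5 `locs` or headered CSV): spot detection, maximum-likelihood PSF
fitting and drift correction are upstream concerns. Two processing steps
are reproduced here:

* **Ellipticity filter**: localizations with ellipticity > 0.6 are removed
  (the 0.6 boundary itself is kept). Ellipticity is defined as
  `1 − min(sx, sy) / max(sx, sy)`; other conventions exist, so a
  pre-computed `ellipticity` column takes precedence when present.
* **Rendering**: a histogram on a 16× oversampled grid — 8 nm render
  pixels from 128 nm camera pixels — with floor binning; total counts
  equal the number of localizations before bit-depth clipping. Counts are
  kept natively at 16 bits; an 8-bit export (counts clipped at 255)
  reproduces the 8-bit PNG convention exactly when needed. An optional
  Gaussian blur of the histogram is available but plain histogram is the
  default.

Sparse inputs from real acquisitions use the *first n* frames
(`select_frames(..., mode = "first")`), matching how an accelerated
acquisition would actually stop early; simulation uses random subsets.

## Training triplets

Full fields are cut by a regular 256 × 256 grid (trailing partials
dropped). Tiles whose mean intensity falls below `alpha` (default 1.0)
times the whole-image mean are excluded — they carry too little structure
to supervise on. The keep/drop mask is derived from the dense channel only
and applied to all three channels, keeping triplets aligned. Each channel
is then normalized to its own uncut-field maximum, so the brightest
surviving pixel of a field maps to exactly 1. Train/test splitting is done
at the source-field level so no field contributes tiles to both sides.

## The network

A classic encoder–decoder with skip connections: counting the input stage,
four downsampling stages, four upsampling stages, and the output stage, the
default network has 10 layers. Concretely each encoder stage applies two
3 × 3 same-padded ReLU convolutions and a 2 × 2 max-pool; channel widths
start at `base_channels` = 64 and double per stage; the decoder mirrors
this with 2 × 2 stride-2 transposed convolutions, concatenation with the
matching encoder activation, and two more convolutions; a linear 1 × 1
convolution produces the single-channel output. This configuration
instantiates 31,030,593 trainable parameters (31,031,169 with two input
channels) — slightly more than 31 million. The transposed-convolution
up-path and the absence of batch normalization are deliberate so that the
parameter count is exactly reproducible from the layer table.

Three variants differ only in input assembly: `"3000"` (sparse render
alone), `"WF"` (widefield alone), `"WF+3000"` (widefield and sparse as two
channels). The target is always the dense channel.

Training minimizes mean squared error on [0, 1] intensities — the same
scale the PSNR/RMSE evaluation uses — with Adam (default learning rate
1e-4, batch 4). The reference schedule is 2,000 epochs on real triplets,
2,000 more on simulated triplets, and a 500-epoch real fine-tune;
`paper_protocol()` echoes these constants. The numerical backend is
written with RcppArmadillo: single-precision im2col + GEMM convolutions,
so training runs at useful speed on one CPU; gradients are verified
against central finite differences in the test suite (away from the
ReLU/max-pool kinks, where a finite difference straddling the kink may
legitimately disagree with the subgradient).

Initialization is He-normal for ReLU layers and Xavier for the linear
output, seeded; shuffling is seeded; training is bitwise reproducible for
a fixed seed and thread configuration (single-threaded BLAS).

## Evaluation protocol

Images are affinely mapped to [0, 255] (for [0, 1]-normalized tiles,
multiplication by 255), then:

* `RMSE = sqrt(mean((GT − OP)^2))`
* `PSNR = 100` when RMSE = 0, else `20·log10(255 / RMSE)` — the piecewise
  form makes the identical-pair case well-defined.
* `SSIM` is *global* (whole-image moments, no sliding window):
  `[(2 μ1 μ2 + c1)(2 cov + c2)] / [(μ1² + μ2² + c1)(σ1² + σ2² + c2)]`
  with population (divide-by-*n*) moments and
  `c1 = (0.01·255)², c2 = (0.03·255)²`. The doubled covariance in the
  numerator is what makes SSIM equal exactly 1 for identical images —
  the defining property of the score; a variant with a single
  `cov + c2` numerator term is available as `formula = "printed"` for
  comparison, but under it identical images score below 1, so it is not
  the default. SSIM is bounded above by 1; the lower bound is **not**
  guaranteed (anti-correlated images can score negative), and the package
  asserts only the upper bound.

Models are compared across test images with a two-independent-sample
t-test (pooled-variance Student test by default, Welch selectable), with
the usual `***` = p < 0.001 convention.

## Desk-scale experiment sizes

The test suite demonstrates the core claim — a trained network restores
dense structure from one-tenth of the frames better than the raw sparse
input — at reduced scale chosen once as this package's standard desk
protocol: 200 simulated triplets on 64 × 64 tiles (`field_width` =
`tile_size` = 64, so boundary-entering filaments populate the whole tile
within 50 frames of half-pixel steps), widefield σ = 5 px through an 8-px
grid (the same 8× ratio as 256/32), 10% sparse fraction; a reduced network
(depth 3, base 16, ~0.48 M parameters) trained 200 epochs with Adam at
1e-3, batch 4; 180/20 train/test split. On the 20 held-out tiles the
reconstruction must beat the sparse input on mean PSNR, mean SSIM and mean
RMSE simultaneously. Smaller configurations (32-px tiles, depth 2) are
used for gradient checks, overfit smoke tests and the end-to-end pipeline
test.

## Numerical and degenerate-case decisions

* Gaussian blurs use a kernel radius of 4σ and exact mirror reflection;
  blur of a zero image is zero, of a constant image constant, and an
  interior point spreads into a unit-mass spot.
* Floor binning is half-open, so no localization is counted twice.
* An empty frame subset renders an all-zero image rather than erroring;
  a sparse fraction that selects less than one frame is an error.
* A constant image with no declared intensity range cannot be mapped to
  [0, 255] (ambiguous affine) and errors; declaring the range resolves it.
* `sparse_fraction` × `n_frames` is rounded half-up.
* Blank channels (all-zero uncut maximum) are contract errors in real-data
  normalization; the simulator leaves all-zero tiles as zeros.
* Identical constant groups in `compare_groups()` return statistic 0,
  p = 1 (the t denominator vanishes there).

## Known limitations

* Simulated filaments are thinner than real microtubules and noise-free;
  models trained purely on simulation will not transfer to real data
  without fine-tuning.
* The CPU backend is practical for desk-scale tiles (tens of minutes for
  the protocols above), not for 2,000-epoch runs on thousands of 256-px
  triplets.
* HDF5 ingestion bridges through the system `python`/h5py; CSV needs no
  bridge.
* Only 2-D, single-channel-output reconstruction is supported.
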