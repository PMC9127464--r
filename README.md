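# upaint

Accelerated DNA-PAINT super-resolution reconstruction in R.

DNA-PAINT (and single-molecule localization microscopy in general) builds a
super-resolution image by accumulating sparse single-emitter localizations
over tens of thousands of camera frames — often close to an hour per field.
`upaint` shortens this by learning the mapping from a **sparse**
localization render (few frames, *n*) — optionally paired with a
diffraction-limited **widefield** image — to the **dense** render a full
acquisition (*N* frames, *N* ≫ *n*) would give:

* a random-walk **microtubule simulator** that manufactures aligned
  (widefield, sparse, dense) training triplets — filaments enter from the
  field boundary and take fixed half-pixel steps toward the center with
  normally perturbed headings; the dense truth is the σ = 1.25 px blurred
  all-frame overlay, the widefield a σ = 20 px blur through a 32-px grid,
  the sparse channel a 10% random frame subset;
* **localization-table tooling**: Picasso-style HDF5 / CSV readers, the
  ellipticity > 0.6 quality cut, first-*n*/random frame subsetting, and
  16×-oversampled histogram rendering (8 nm pixels from 128 nm camera
  pixels);
* **dataset preparation**: 256 × 256 tiling, exclusion of tiles below the
  whole-image mean intensity, normalization to the uncut-image maximum,
  source-level train/test splitting;
* a **U-Net** (4 down + 4 up stages + input and output layers = 10 layers,
  31,030,593 parameters at the defaults) with an RcppArmadillo
  backend — single-precision im2col/GEMM convolutions, Adam, MSE loss —
  trained entirely on the CPU, in the `"3000"` (sparse input), `"WF"`
  (widefield input) and `"WF+3000"` (both) variants;
* the **evaluation protocol**: intensities mapped to [0, 255], then
  RMSE = √mean((GT−OP)²), piecewise PSNR (= 100 at RMSE 0, else
  20·log₁₀(255/RMSE)), and global single-window SSIM
  (2μ₁μ₂+c₁)(2cov+c₂) / ((μ₁²+μ₂²+c₁)(σ₁²+σ₂²+c₂)), plus
  two-independent-sample t-tests between models.

Audience: microscopists and image-analysis developers who want a
self-contained, inspectable R implementation of the sparse-to-dense
reconstruction workflow — every stage from simulation to metrics is a
plain exported function.

## Worked example

Simulate 60 fields, train a reduced network on 48 of them to densify 10%
sparse renders, and evaluate on the 12 held-out tiles:

```r
library(upaint)

cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                  wf_blur_sd = 5, n_frames = 50, seed = 42)
triplets <- generate_dataset(cfg, 60)
split <- split_dataset(triplets, test_fraction = 0.2, seed = 43)

model <- build_network(unet_spec(in_channels = 1, depth = 3,
                                 base_channels = 16, tile_size = 64),
                       seed = 44)
model
#> <upaint_unet> in=1, depth=3, base=16 (3 down + 3 up + input + output = 8 layers), 481,745 parameters

res <- train_network(model, split$train,
                     train_config(epochs = 60, batch_size = 4,
                                  learning_rate = 1e-3, seed = 45),
                     variant = "3000")
c(res$history[1], res$history[60])
#> [1] 0.02305 0.00030

gts    <- lapply(split$test, `[[`, "dense")
recons <- lapply(split$test, function(tp) predict(res$model, sparse = tp$sparse))
evaluate_batch(gts, recons)$summary
#>   metric       mean         sd
#> 1   rmse 25.6495245 9.51273973
#> 2   psnr 20.3833916 2.73558654
#> 3   ssim  0.8359402 0.08638391

evaluate_batch(gts, lapply(split$test, `[[`, "sparse"))$summary  # raw sparse baseline
#>   metric        mean          sd
#> 1   rmse 48.98018762 8.193764070
#> 2   psnr 14.43710752 1.408993206
#> 3   ssim  0.04343707 0.005254752
```

After one minute of CPU training the reconstruction already beats the raw
sparse input on every metric: RMSE halves (49 → 26 on the 0–255 scale),
PSNR gains ~6 dB, and SSIM rises from 0.04 to 0.84 — the sparse render
shares almost no structural signal with the dense truth, the reconstruction
most of it. The model comparison convention:

```r
compare_groups(evaluate_batch(gts, recons)$per_image$psnr,
               evaluate_batch(gts, lapply(split$test, `[[`, "sparse"))$per_image$psnr)
#> <upaint_comparison> t = 6.6941, df = 22.00, p = 9.94e-07 (***)
```

An end-to-end run (simulate → split → train → predict → evaluate, with a
hashed replay manifest) is one call:

```r
run_pipeline(demo_run_config(n_sets = 20, epochs = 50), out_dir = "demo_run")
```

and a thin command-line front-end with `simulate / render / prepare /
train / predict / evaluate / run` subcommands lives at
`inst/cli/upaint.R`.

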