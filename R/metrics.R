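# Reconstruction-quality protocol: intensities are mapped to [0, 255], then
# RMSE, a piecewise PSNR (100 exactly at zero error), and a global
# (whole-image) SSIM are computed; models are compared across test images
# with a two-independent-sample t-test.

#' Map image intensities to the \[0, 255\] evaluation scale
#'
#' Affine map of the declared intensity range onto \[0, 255\]; for
#' \[0, 1\]-normalized tiles this is multiplication by 255. Without a
#' declared range the observed min/max are used, which is ambiguous for a
#' constant image (an error).
#' @param x matrix or `upaint_image`.
#' @param range length-2 declared intensity range, or `NULL` to use the
#'   observed range.
#' @return matrix on \[0, 255\].
#' @export
map_to_255 <- function(x, range = NULL) {
  m <- as_matrix(x)
  if (!all(is.finite(m))) stop("image has non-finite intensities")
  if (is.null(range)) {
    range <- c(min(m), max(m))
    if (diff(range) == 0)
      stop("constant image with no declared range: the [0,255] map is ",
           "ambiguous; pass 'range' explicitly")
  }
  stopifnot(length(range) == 2, range[2] > range[1])
  (m - range[1]) * (255 / (range[2] - range[1]))
}

.check_pair <- function(gt, op) {
  if (!all(dim(gt) == dim(op)))
    stop("image shapes differ: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(op), collapse = "x"))
}

#' Root-mean-square error between ground truth and output
#'
#' `sqrt(mean((GT - OP)^2))` over all pixels; symmetric in its arguments.
#' Both images should already be on the \[0, 255\] scale.
#' @param gt,op numeric matrices of identical shape.
#' @return nonnegative scalar.
#' @export
metric_rmse <- function(gt, op) {
  gt <- as_matrix(gt)
  op <- as_matrix(op)
  .check_pair(gt, op)
  sqrt(mean((gt - op)^2))
}

#' Piecewise peak signal-to-noise ratio
#'
#' 100 when RMSE is exactly 0 (identical images), otherwise
#' `20 * log10(255 / RMSE)`.
#' @inheritParams metric_rmse
#' @return PSNR score; equals 100 iff the images are identical.
#' @export
metric_psnr <- function(gt, op) {
  r <- metric_rmse(gt, op)
  if (r == 0) 100 else 20 * log10(255 / r)
}

#' Global (whole-image) structural similarity
#'
#' Uses whole-image means, variances and covariance (no sliding window):
#' \deqn{SSIM = \frac{(2\mu_{GT}\mu_{OP} + c_1)(2\,cov + c_2)}
#'                 {(\mu_{GT}^2 + \mu_{OP}^2 + c_1)(\sigma_{GT}^2 + \sigma_{OP}^2 + c_2)}}
#' with population (divide-by-n) moments by default. The default doubled
#' covariance numerator makes SSIM reach exactly 1 for identical images;
#' `formula = "printed"` uses a single `cov + c2` numerator term instead
#' (for comparison with that variant, under which identical images score
#' below 1). SSIM is bounded above by 1; the lower bound is not guaranteed
#' (anti-correlated images can go negative).
#' @inheritParams metric_rmse
#' @param c1,c2 small positive stabilizing constants; defaults are the
#'   conventional `(0.01 * 255)^2` and `(0.03 * 255)^2` for a 255 dynamic
#'   range.
#' @param formula `"identity"` (default, doubled covariance) or
#'   `"printed"`.
#' @param moments `"population"` (divide by n, default) or `"sample"`.
#' @return SSIM value, at most 1 under the default formula.
#' @export
metric_ssim <- function(gt, op, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                        formula = c("identity", "printed"),
                        moments = c("population", "sample")) {
  formula <- match.arg(formula)
  moments <- match.arg(moments)
  if (c1 <= 0 || c2 <= 0) stop("'c1' and 'c2' must be positive")
  gt <- as_matrix(gt)
  op <- as_matrix(op)
  .check_pair(gt, op)
  n <- length(gt)
  mu1 <- mean(gt)
  mu2 <- mean(op)
  denom_n <- if (moments == "population") n else n - 1
  v1 <- sum((gt - mu1)^2) / denom_n
  v2 <- sum((op - mu2)^2) / denom_n
  cv <- sum((gt - mu1) * (op - mu2)) / denom_n
  num2 <- if (formula == "identity") 2 * cv + c2 else cv + c2
  ((2 * mu1 * mu2 + c1) * num2) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}

#' Evaluate one reconstruction against its ground truth
#'
#' Maps both images to \[0, 255\] via the declared range, then computes
#' RMSE, piecewise PSNR and global SSIM.
#' @param gt,op aligned images (matrices or `upaint_image`s).
#' @param range declared intensity range shared by both images (default
#'   \[0, 1\], the normalized-tile convention).
#' @inheritParams metric_ssim
#' @return a list of class `upaint_metrics` with fields `rmse`, `psnr`,
#'   `ssim`, `c1`, `c2`, `n_pixels`.
#' @export
evaluate_pair <- function(gt, op, range = c(0, 1), c1 = (0.01 * 255)^2,
                          c2 = (0.03 * 255)^2,
                          formula = c("identity", "printed")) {
  g <- map_to_255(gt, range)
  o <- map_to_255(op, range)
  structure(list(rmse = metric_rmse(g, o), psnr = metric_psnr(g, o),
                 ssim = metric_ssim(g, o, c1, c2, formula),
                 c1 = c1, c2 = c2, n_pixels = length(g)),
            class = "upaint_metrics")
}

#' @export
print.upaint_metrics <- function(x, ...) {
  cat(sprintf("<upaint_metrics> RMSE %.4f | PSNR %.4f | SSIM %.6f (n = %d px)\n",
              x$rmse, x$psnr, x$ssim, x$n_pixels))
  invisible(x)
}

#' Evaluate a batch of reconstructions
#'
#' One [evaluate_pair()] per (gt, op) pair, plus the per-metric mean and
#' standard deviation across images (the error-bar convention for test
#' sets).
#' @param gts,ops lists of aligned images, same length.
#' @inheritParams evaluate_pair
#' @return `list(per_image = data.frame, summary = data.frame)`.
#' @export
evaluate_batch <- function(gts, ops, range = c(0, 1), c1 = (0.01 * 255)^2,
                           c2 = (0.03 * 255)^2) {
  stopifnot(length(gts) == length(ops), length(gts) >= 1)
  rows <- mapply(function(g, o) {
    m <- evaluate_pair(g, o, range, c1, c2)
    data.frame(rmse = m$rmse, psnr = m$psnr, ssim = m$ssim)
  }, gts, ops, SIMPLIFY = FALSE)
  per <- do.call(rbind, rows)
  per$image <- seq_len(nrow(per))
  summ <- data.frame(
    metric = c("rmse", "psnr", "ssim"),
    mean = c(mean(per$rmse), mean(per$psnr), mean(per$ssim)),
    sd = c(sd(per$rmse), sd(per$psnr), sd(per$ssim)))
  list(per_image = per[, c("image", "rmse", "psnr", "ssim")],
       summary = summ)
}

#' Compare two models' per-image metric values
#'
#' Two-independent-sample t-test (pooled-variance Student test by default;
#' `var_equal = FALSE` gives Welch). When both groups are identical
#' constants the statistic is 0 and p = 1 by convention.
#' @param a,b numeric vectors of per-image metric values (length >= 2
#'   each).
#' @param var_equal pool the variances (classic two-sample t-test)?
#' @return a list of class `upaint_comparison`: `statistic`, `p_value`,
#'   `df`, `mean_a`, `mean_b`, `method`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    res <- list(statistic = 0, p_value = 1,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b),
                method = "degenerate (identical constant groups)")
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter),
                mean_a = mean(a), mean_b = mean(b), method = tt$method)
  }
  structure(res, class = "upaint_comparison")
}

#' @export
print.upaint_comparison <- function(x, ...) {
  stars <- if (x$p_value < 0.001) "***"
           else if (x$p_value < 0.01) "**"
           else if (x$p_value < 0.05) "*" else "n.s."
  cat(sprintf("<upaint_comparison> t = %.4f, df = %.2f, p = %.3g (%s)\n",
              x$statistic, x$df, x$p_value, stars))
  invisible(x)
}

#' Reference protocol constants
#'
#' The published workflow constants in one place: the simulation defaults
#' (500 frames, ~10 boundary trajectories, sigma 1.25 / 20 px blurs, 32-px
#' widefield grid, 256-px tiles, 10% sparse fraction), the render defaults
#' (16x oversampling, 8 nm target pixels), the ellipticity cut 0.6, the
#' default U-Net (10 layers, > 31 million parameters), and the
#' 2,000 / 2,000 / 500-epoch training schedule (real, then simulated, then
#' real fine-tune).
#' @return a named list of default configuration objects and constants.
#' @export
paper_protocol <- function() {
  list(sim = sim_config(),
       render = render_spec(),
       max_ellipticity = 0.6,
       unet = unet_spec(),
       train = train_config(),
       epoch_schedule = c(real = 2000L, simulated = 2000L,
                          real_finetune = 500L))
}
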