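# Evaluation protocol: [0,255] mapping, RMSE, piecewise PSNR, global SSIM,
# batch aggregation and two-sample comparison, all cross-checked against
# naive-loop oracles.

test_that("the [0,255] map is the declared affine transform", {
  m <- matrix(c(0, 0.5, 1, 0.25), 2)
  expect_equal(map_to_255(m, c(0, 1)), m * 255)
  expect_equal(map_to_255(m, c(0, 1))[1, 2], 255)
  expect_equal(map_to_255(matrix(0.5, 2, 2), c(0, 1))[1, 1], 127.5)
  # already-[0,255] image with declared range is unchanged
  m255 <- matrix(c(0, 100, 200, 255), 2)
  expect_equal(map_to_255(m255, c(0, 255)), m255)
  # zero tile with declared range stays zero; undeclared constant errors
  expect_equal(map_to_255(matrix(0, 3, 3), c(0, 1)), matrix(0, 3, 3))
  expect_error(map_to_255(matrix(1, 3, 3)), "ambiguous")
})

test_that("RMSE and PSNR follow their closed forms", {
  z <- matrix(0, 4, 4)
  expect_equal(metric_rmse(z, z), 0)
  expect_equal(metric_psnr(z, z), 100)
  expect_equal(metric_rmse(z, matrix(255, 4, 4)), 255)
  expect_equal(metric_psnr(z, matrix(255, 4, 4)), 0)  # 20*log10(1)
  op <- z + 2.55
  expect_equal(metric_psnr(z, op), 40)  # 20*log10(100)
  expect_error(metric_rmse(z, matrix(0, 3, 3)), "shape")
})

test_that("PSNR is consistent with RMSE and monotone in noise amplitude", {
  set.seed(41)
  gt <- matrix(runif(32 * 32, 0, 255), 32)
  noise <- matrix(rnorm(32 * 32), 32)
  rmses <- psnrs <- numeric(5)
  for (a in 1:5) {
    op <- gt + a * 5 * noise
    rmses[a] <- metric_rmse(gt, op)
    psnrs[a] <- metric_psnr(gt, op)
    expect_equal(psnrs[a], 20 * log10(255 / rmses[a]))
  }
  expect_true(all(diff(rmses) > 0))
  expect_true(all(diff(psnrs) < 0))
})

test_that("SSIM reaches exactly 1 for identical images and handles degenerate pairs", {
  set.seed(42)
  m <- matrix(runif(64 * 64, 0, 255), 64)
  expect_equal(metric_ssim(m, m), 1, tolerance = 1e-9)
  # both constant zero: numerator and denominator reduce to c1*c2
  z <- matrix(0, 8, 8)
  expect_equal(metric_ssim(z, z), 1)
  # the printed single-covariance variant scores identical images below 1
  expect_lt(metric_ssim(m, m, formula = "printed"), 1)
  expect_error(metric_ssim(m, m, c1 = 0), "positive")
})

test_that("all three metrics match brute-force oracles on random pairs", {
  set.seed(43)
  for (k in 1:20) {
    gt <- matrix(runif(32 * 32, 0, 255), 32)
    op <- matrix(runif(32 * 32, 0, 255), 32)
    expect_equal(metric_rmse(gt, op), oracle_rmse(gt, op), tolerance = 1e-9)
    expect_equal(metric_psnr(gt, op), oracle_psnr(gt, op), tolerance = 1e-9)
    expect_equal(metric_ssim(gt, op), oracle_ssim(gt, op), tolerance = 1e-9)
    # symmetry
    expect_equal(metric_rmse(gt, op), metric_rmse(op, gt))
    expect_equal(metric_ssim(gt, op), metric_ssim(op, gt))
  }
})

test_that("SSIM never exceeds 1 across a stress set of pairs", {
  set.seed(44)
  vals <- c()
  for (k in 1:50) {
    gt <- matrix(runif(32 * 32, 0, 255), 32)
    pairs <- list(gt,                               # identical
                  matrix(runif(32 * 32, 0, 255), 32),  # independent
                  255 - gt,                         # anti-correlated
                  0.5 * gt + 10)                    # scaled/shifted
    vals <- c(vals, vapply(pairs, function(op) metric_ssim(gt, op),
                           numeric(1)))
  }
  expect_true(all(vals <= 1 + 1e-12))
})

test_that("evaluate_pair composes mapping and metrics into a report", {
  set.seed(45)
  m <- matrix(runif(16 * 16), 16)
  rep_id <- evaluate_pair(m, m)
  expect_equal(rep_id$rmse, 0)
  expect_equal(rep_id$psnr, 100)
  expect_equal(rep_id$ssim, 1, tolerance = 1e-9)
  expect_equal(rep_id$n_pixels, 256)
  rep2 <- evaluate_pair(m, matrix(runif(16 * 16), 16))
  expect_true(all(is.finite(unlist(rep2[c("rmse", "psnr", "ssim")]))))
  expect_equal(rep2$c1, (0.01 * 255)^2)
})

test_that("batch evaluation reports per-image rows with mean and sd", {
  set.seed(46)
  gts <- replicate(36, matrix(runif(16 * 16), 16), simplify = FALSE)
  ops <- lapply(gts, function(g) pmin(pmax(g + rnorm(256, 0, 0.05), 0), 1))
  ev <- evaluate_batch(gts, ops)
  expect_equal(nrow(ev$per_image), 36)
  expect_equal(ev$summary$metric, c("rmse", "psnr", "ssim"))
  expect_true(all(is.finite(ev$summary$mean)))
  expect_true(all(is.finite(ev$summary$sd)))
  expect_equal(ev$summary$mean[1], mean(ev$per_image$rmse))
})

test_that("two-sample comparison matches a hand-computed t statistic", {
  # pooled-variance t on a 3+3 toy set, computed from first principles
  a <- c(1, 2, 3)
  b <- c(5, 6, 10)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  cmp <- compare_groups(a, b)
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  # identical constant groups: statistic 0, p = 1
  cmp0 <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)
  # widely separated groups reach the *** convention
  set.seed(47)
  x <- rnorm(10, 0, 0.1)
  y <- rnorm(10, 5, 0.1)
  expect_lt(compare_groups(x, y)$p_value, 0.001)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
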