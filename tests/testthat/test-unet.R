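# Network architecture, parameter accounting, analytic gradients vs finite
# differences, training behaviour, inference contracts.

test_that("parameter counts match hand-enumerated closed forms", {
  # depth 1, base 2, in 1: enumerate every convolution by hand
  #   enc1_1 3x3 1->2: 9*1*2+2 = 20      enc1_2 3x3 2->2: 9*2*2+2 = 38
  #   bott_1 3x3 2->4: 9*2*4+4 = 76      bott_2 3x3 4->4: 9*4*4+4 = 148
  #   up1  2x2 4->2:  4*4*2+2 = 34       dec1_1 3x3 4->2: 9*4*2+2 = 74
  #   dec1_2 3x3 2->2: 38                out   1x1 2->1:  2+1 = 3
  expect_equal(count_parameters(unet_spec(1, depth = 1, base_channels = 2,
                                          tile_size = 8)), 431)
  # depth 2, base 4, in 1 (same enumeration, deeper): 7397
  expect_equal(count_parameters(unet_spec(1, depth = 2, base_channels = 4,
                                          tile_size = 16)), 7397)
  # a built model agrees with its spec, and the backend agrees with both
  spec <- unet_spec(1, depth = 2, base_channels = 4, tile_size = 16)
  model <- build_network(spec, seed = 1)
  expect_equal(count_parameters(model), 7397)
  expect_equal(upaint:::unet_nparams_ptr(upaint:::.unet_ptr(model)), 7397)
})

test_that("the default architecture has 10 layers and >31M parameters", {
  spec <- unet_spec()
  expect_equal(spec$depth * 2 + 2, 10)  # 4 down + 4 up + input + output
  expect_gt(count_parameters(spec), 31e6)
  # adding an input channel adds exactly kernel_area x base_channels weights
  expect_equal(count_parameters(unet_spec(in_channels = 2)) -
                 count_parameters(unet_spec(in_channels = 1)), 9 * 64)
  expect_error(unet_spec(tile_size = 250), "divisible")
})

test_that("a frozen model reports zero trainable parameters", {
  m <- build_network(unet_spec(1, depth = 1, base_channels = 2,
                               tile_size = 8), seed = 2)
  expect_equal(count_parameters(freeze_network(m)), 0)
  expect_error(train_network(freeze_network(m), list(), train_config()),
               "frozen")
})

test_that("forward pass preserves spatial shape and stays finite on zeros", {
  for (ts in c(16, 32)) {
    m <- build_network(unet_spec(1, depth = 2, base_channels = 4,
                                 tile_size = ts), seed = 3)
    out <- predict(m, sparse = matrix(0, ts, ts))
    expect_equal(dim(out), c(ts, ts))
    expect_true(all(is.finite(out)))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("analytic gradients match central finite differences", {
  spec <- unet_spec(1, depth = 1, base_channels = 2, tile_size = 8)
  model <- build_network(spec, seed = 4)
  set.seed(5)
  X <- array(runif(64), c(8, 8, 1, 1))
  Y <- array(runif(64), c(8, 8, 1, 1))
  ptr <- upaint:::.unet_ptr(model)
  lg <- upaint:::unet_lossgrad_ptr(ptr, X, Y)
  h <- 5e-3
  mismatch <- 0L
  n_checked <- 0L
  for (k in seq_along(model$weights)) {
    nw <- length(model$weights[[k]]$W)
    for (i in sample(nw, min(3, nw))) {
      wp <- model$weights; wp[[k]]$W[i] <- wp[[k]]$W[i] + h
      wm <- model$weights; wm[[k]]$W[i] <- wm[[k]]$W[i] - h
      upaint:::unet_set_weights_ptr(ptr, unname(wp))
      lp <- upaint:::unet_lossgrad_ptr(ptr, X, Y)$loss
      upaint:::unet_set_weights_ptr(ptr, unname(wm))
      lm <- upaint:::unet_lossgrad_ptr(ptr, X, Y)$loss
      fd <- (lp - lm) / (2 * h)
      an <- lg$grads[[k]]$dW[i]
      ok <- abs(fd - an) < 0.1 * max(abs(fd), abs(an)) + 1e-3
      mismatch <- mismatch + !ok
      n_checked <- n_checked + 1L
    }
  }
  # ReLU/max-pool kinks make the loss piecewise-smooth, so a central
  # difference straddling a kink may legitimately disagree with the
  # subgradient at a few sampled weights; the overwhelming majority must
  # match tightly.
  expect_gte(n_checked, 20)
  expect_lte(mismatch, 2)
})

test_that("a single triplet is memorized (overfit smoke test)", {
  cfg <- desk_config(seed = 6, field_width = 32L, tile_size = 32L)
  tp <- generate_dataset(cfg, 1)
  m <- build_network(unet_spec(1, depth = 2, base_channels = 8,
                               tile_size = 32), seed = 7)
  res <- train_network(m, tp,
                       train_config(epochs = 500, batch_size = 1,
                                    learning_rate = 1e-3, seed = 8),
                       variant = "3000")
  expect_length(res$history, 500)
  expect_lt(res$history[500], 0.01 * res$history[1])
})

test_that("epoch losses fall below the first epoch on a simulated dataset", {
  cfg <- desk_config(seed = 9, field_width = 32L, tile_size = 32L)
  tp <- generate_dataset(cfg, 200)
  m <- build_network(unet_spec(1, depth = 2, base_channels = 8,
                               tile_size = 32), seed = 10)
  res <- train_network(m, tp,
                       train_config(epochs = 50, batch_size = 4,
                                    learning_rate = 1e-3, seed = 11),
                       variant = "3000")
  expect_lt(res$history[50], res$history[1])
  expect_true(all(res$history[45:50] < res$history[1]))
})

test_that("training is deterministic under a fixed seed", {
  cfg <- desk_config(seed = 12, field_width = 32L, tile_size = 32L)
  tp <- generate_dataset(cfg, 4)
  run <- function() {
    m <- build_network(unet_spec(1, depth = 2, base_channels = 4,
                                 tile_size = 32), seed = 13)
    train_network(m, tp, train_config(epochs = 5, batch_size = 2,
                                      learning_rate = 1e-3, seed = 14),
                  variant = "3000")
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$model$weights, b$model$weights)
})

test_that("variant selection enforces the channel contract", {
  cfg <- desk_config(seed = 15, field_width = 32L, tile_size = 32L)
  tp <- generate_dataset(cfg, 2)
  m2 <- build_network(unet_spec(2, depth = 2, base_channels = 4,
                                tile_size = 32), seed = 16)
  expect_error(train_network(m2, tp, train_config(epochs = 1),
                             variant = "3000"), "channel")
  expect_error(predict(m2, sparse = tp[[1]]$sparse), "channel")
  out <- predict(m2, sparse = tp[[1]]$sparse, widefield = tp[[1]]$widefield)
  expect_equal(dim(out), c(32, 32))
  expect_error(train_config(epochs = 0), "at least 1")
  expect_error(predict(m2, sparse = tp[[1]]$sparse + 2,
                       widefield = tp[[1]]$widefield), "normalized")
})

test_that("checkpoints round-trip weights and reproduce predictions", {
  cfg <- desk_config(seed = 17, field_width = 32L, tile_size = 32L)
  tp <- generate_dataset(cfg, 1)
  m <- build_network(unet_spec(1, depth = 2, base_channels = 4,
                               tile_size = 32), seed = 18)
  res <- train_network(m, tp, train_config(epochs = 5, batch_size = 1,
                                           learning_rate = 1e-3, seed = 19),
                       variant = "3000")
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(res$model, ck, config = train_config(epochs = 5))
  m2 <- load_checkpoint(ck)
  expect_identical(m2$weights, res$model$weights)
  expect_equal(predict(m2, sparse = tp[[1]]$sparse),
               predict(res$model, sparse = tp[[1]]$sparse))
  side <- jsonlite::read_json(paste0(ck, ".json"))
  expect_equal(side$spec$depth, 2)
})
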