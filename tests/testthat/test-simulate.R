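# Random-walk microtubule simulator: geometric invariants, count
# conservation, rendering chain, determinism.

test_that("trajectories start on the boundary and keep an exact step length", {
  cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                    n_trajectories = 20, n_frames = 40, seed = 42)
  traj <- simulate_trajectories(cfg)
  expect_length(traj$points, 20)
  for (p in traj$points) {
    expect_equal(nrow(p), 40)
    expect_identical(p[, "frame"], as.numeric(0:39))
    on_boundary <- p[1, "x"] %in% c(0, 64) || p[1, "y"] %in% c(0, 64)
    expect_true(on_boundary)
    # brute-force pairwise distances between consecutive points
    for (r in 2:nrow(p)) {
      d <- sqrt((p[r, "x"] - p[r - 1, "x"])^2 + (p[r, "y"] - p[r - 1, "y"])^2)
      expect_lt(abs(d - 0.5), 1e-9)
    }
  }
})

test_that("paper-scale defaults give 10 trajectories of 500 points", {
  cfg <- sim_config(seed = 1)
  traj <- simulate_trajectories(cfg)
  expect_length(traj$points, 10)
  expect_true(all(vapply(traj$points, nrow, integer(1)) == 500L))
})

test_that("a single-frame run yields one boundary point per trajectory", {
  cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                    n_frames = 1, sparse_fraction = 1, seed = 3)
  traj <- simulate_trajectories(cfg)
  expect_true(all(vapply(traj$points, nrow, integer(1)) == 1L))
})

test_that("noise-free trajectories are colinear toward the field center", {
  cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                    n_trajectories = 1, n_frames = 30,
                    heading_noise_sd = 0, seed = 9)
  p <- simulate_trajectories(cfg)$points[[1]]
  # perpendicular residual from the start -> center segment
  dir <- c(32 - p[1, "x"], 32 - p[1, "y"])
  dir <- dir / sqrt(sum(dir^2))
  res <- (p[, "x"] - p[1, "x"]) * dir[2] - (p[, "y"] - p[1, "y"]) * dir[1]
  expect_lt(max(abs(res)), 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(step_length = 0), "step_length")
  expect_error(sim_config(n_frames = -1), "n_frames")
  expect_error(sim_config(sparse_fraction = 1.5), "sparse_fraction")
  expect_error(sim_config(tile_size = 250, wf_small_size = 32), "divide")
  expect_error(sim_config(field_width = 128, tile_size = 256), "tile_size")
})

test_that("overlay conserves in-field counts and uses floor binning", {
  cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                    n_trajectories = 10, n_frames = 50, seed = 5)
  traj <- simulate_trajectories(cfg)
  all_frames <- 0:49
  ov <- overlay_frames(traj, all_frames)
  expect_equal(sum(as_matrix(ov)), oracle_count_infield(traj, all_frames))
  # empty subset -> zero image, not an error
  expect_equal(sum(as_matrix(overlay_frames(traj, integer(0)))), 0)
  # hand binning: (3.2, 7.9) -> cell (x=3, y=7), matrix entry [8, 4]
  tr <- manual_traj(list(cbind(frame = 0, x = 3.2, y = 7.9)), 10)
  m <- as_matrix(overlay_frames(tr, 0))
  expect_equal(sum(m), 1)
  expect_equal(m[8, 4], 1)
})

test_that("overlay is monotone under frame-subset inclusion", {
  cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                    n_frames = 40, seed = 6)
  traj <- simulate_trajectories(cfg)
  set.seed(1)
  for (k in 1:5) {
    b_set <- sort(sample(0:39, 20))
    a_set <- sort(sample(b_set, 8))
    a <- as_matrix(overlay_frames(traj, a_set))
    b <- as_matrix(overlay_frames(traj, b_set))
    expect_true(all(a <= b))
  }
})

test_that("ground-truth rendering blurs, crops and conserves mass", {
  cfg <- sim_config(field_width = 96, tile_size = 64, wf_small_size = 8,
                    seed = 7)
  # zero overlay -> zero ground truth
  zero <- upaint_image(matrix(0, 96, 96), kind = "overlay")
  expect_equal(sum(as_matrix(make_ground_truth(zero, cfg))), 0)
  # an interior point spreads into a unit-mass blurred spot
  one <- matrix(0, 96, 96); one[48, 48] <- 3
  gt <- make_ground_truth(upaint_image(one, kind = "overlay"), cfg)
  expect_equal(dim(as_matrix(gt)), c(64, 64))
  expect_equal(sum(as_matrix(gt)), 3, tolerance = 1e-6)
  # default chain emits 256-px tiles
  cfg256 <- sim_config(seed = 8)
  traj <- simulate_trajectories(cfg256)
  gt256 <- make_ground_truth(overlay_frames(traj), cfg256)
  expect_equal(dim(as_matrix(gt256)), c(256, 256))
})

test_that("widefield keeps tiles constant, zero and correctly sized", {
  cfg <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                    wf_blur_sd = 5, seed = 10)
  expect_equal(sum(as_matrix(make_widefield(matrix(0, 64, 64), cfg))), 0)
  const <- make_widefield(matrix(2.5, 64, 64), cfg)
  expect_equal(as_matrix(const), matrix(2.5, 64, 64), tolerance = 1e-9)
  cfg256 <- sim_config(seed = 11)
  traj <- simulate_trajectories(cfg256)
  gt <- make_ground_truth(overlay_frames(traj), cfg256)
  wf <- make_widefield(gt, cfg256)
  expect_equal(dim(as_matrix(wf)), c(256, 256))
})

test_that("sparse frame selection matches the configured fraction", {
  cfg <- sim_config(seed = 12)  # 500 frames, 10%
  traj <- simulate_trajectories(cfg)
  sp <- make_sparse(traj, cfg, seed = 13)
  expect_length(attr(sp, "frames"), 50)
  # mode "first" takes frames 0..n-1
  cfg10 <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                      n_frames = 10, sparse_fraction = 0.3, seed = 14)
  tr10 <- simulate_trajectories(cfg10)
  expect_identical(attr(make_sparse(tr10, cfg10, mode = "first"), "frames"),
                   0:2)
  # full fraction reproduces the ground truth exactly
  cfg1 <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                     n_frames = 20, sparse_fraction = 1, seed = 15)
  tr1 <- simulate_trajectories(cfg1)
  expect_equal(as_matrix(make_sparse(tr1, cfg1, seed = 16)),
               as_matrix(make_ground_truth(overlay_frames(tr1), cfg1)))
  # unselectable fraction errors
  cfg_bad <- sim_config(field_width = 64, tile_size = 64, wf_small_size = 8,
                        n_frames = 5, sparse_fraction = 0.1, seed = 17)
  tr_bad <- simulate_trajectories(cfg_bad)
  expect_error(make_sparse(tr_bad, cfg_bad), "below 1")
})

test_that("dataset generation is seed-deterministic with aligned channels", {
  cfg <- desk_config(seed = 18)
  a <- generate_dataset(cfg, 3)
  b <- generate_dataset(cfg, 3)
  expect_identical(a, b)
  for (tp in a) {
    expect_s3_class(tp, "upaint_triplet")
    expect_lte(sum(tp$sparse), sum(tp$dense))
    for (ch in list(tp$widefield, tp$sparse, tp$dense)) {
      expect_gte(min(ch), 0)
      expect_lte(max(ch), 1)
    }
  }
})

test_that("triplets round-trip through 16-bit TIFF files with sidecars", {
  cfg <- desk_config(seed = 19)
  tp <- generate_dataset(cfg, 2)
  dir <- withr::local_tempdir()
  mf <- write_triplets(tp, dir, config = cfg)
  expect_equal(nrow(mf), 2)
  expect_true(all(file.exists(unlist(mf[, c("widefield", "sparse", "dense",
                                            "sidecar")]))))
  back <- read_image(mf$dense[1])
  expect_lte(max(abs(back - tp[[1]]$dense)), 1 / 65535)
  side <- jsonlite::read_json(mf$sidecar[1])
  expect_equal(side$config$n_frames, 50)
})
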