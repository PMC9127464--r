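# Independent brute-force oracles and small fixtures, deliberately written
# with naive loops so they share no code path with the package internals.

oracle_rmse <- function(gt, op) {
  s <- 0
  for (i in seq_len(nrow(gt)))
    for (j in seq_len(ncol(gt)))
      s <- s + (gt[i, j] - op[i, j])^2
  sqrt(s / (nrow(gt) * ncol(gt)))
}

oracle_psnr <- function(gt, op) {
  r <- oracle_rmse(gt, op)
  if (r == 0) 100 else 20 * log10(255 / r)
}

oracle_ssim <- function(gt, op, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  n <- length(gt)
  m1 <- 0; m2 <- 0
  for (v in gt) m1 <- m1 + v
  for (v in op) m2 <- m2 + v
  m1 <- m1 / n; m2 <- m2 / n
  v1 <- 0; v2 <- 0; cv <- 0
  for (k in seq_len(n)) {
    v1 <- v1 + (gt[k] - m1)^2
    v2 <- v2 + (op[k] - m2)^2
    cv <- cv + (gt[k] - m1) * (op[k] - m2)
  }
  v1 <- v1 / n; v2 <- v2 / n; cv <- cv / n
  (2 * m1 * m2 + c1) * (2 * cv + c2) /
    ((m1^2 + m2^2 + c1) * (v1 + v2 + c2))
}

# Count in-field points of the selected frames by explicit iteration.
oracle_count_infield <- function(traj, frames) {
  fw <- traj$field_width
  n <- 0L
  for (p in traj$points)
    for (r in seq_len(nrow(p))) {
      if (!(p[r, "frame"] %in% frames)) next
      if (p[r, "x"] >= 0 && p[r, "x"] < fw &&
          p[r, "y"] >= 0 && p[r, "y"] < fw) n <- n + 1L
    }
  n
}

# Desk-scale simulation settings used across network tests: filaments cross
# a 64-px field in 50 half-pixel steps.
desk_config <- function(seed = NULL, ...) {
  args <- modifyList(list(field_width = 64L, tile_size = 64L,
                          wf_small_size = 8L, wf_blur_sd = 5,
                          n_frames = 50L, n_trajectories = 10L,
                          seed = seed), list(...))
  do.call(sim_config, args)
}

# Hand-built two-point trajectory container for binning tests.
manual_traj <- function(points_list, field_width, step_length = 0.5) {
  structure(list(points = points_list, field_width = field_width,
                 step_length = step_length,
                 n_frames = max(vapply(points_list,
                                       function(p) max(p[, "frame"]) + 1,
                                       numeric(1)))),
            class = "upaint_trajectories")
}
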