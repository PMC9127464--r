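# Random-walk microtubule simulator for DNA-PAINT training data.
#
# Filaments enter from the field boundary and take fixed-length steps whose
# expected heading points at the field center, perturbed each frame by a
# normally distributed angle. Accumulating one localization per filament per
# frame and blurring the overlay gives a dense "ground truth"; a heavy blur
# through a coarse grid emulates the widefield channel; a random frame subset
# gives the sparse channel.

#' Simulation configuration
#'
#' Defaults follow the DNA-PAINT microtubule protocol: ~10 filaments entering
#' from the boundary of a 512-px working field, 500 frames of half-pixel
#' steps, ground truth blurred with sigma 1.25 px and center-cropped to
#' 256x256, widefield derived by a sigma 20 px blur through a 32-px grid,
#' and a 10% sparse frame fraction.
#'
#' @param field_width working grid width in pixels (pre-crop).
#' @param n_trajectories number of filaments per field.
#' @param n_frames number of accumulation frames (one point per filament per
#'   frame).
#' @param step_length per-frame displacement in pixels.
#' @param heading_noise_sd sd (radians) of the normal perturbation applied to
#'   the toward-center heading at every step.
#' @param gt_blur_sd Gaussian sd (px) for the ground-truth render.
#' @param wf_blur_sd Gaussian sd (px) for the widefield blur.
#' @param wf_small_size intermediate widefield grid width (px); must divide
#'   `tile_size`.
#' @param tile_size output tile width (px).
#' @param sparse_fraction fraction of frames kept in the sparse channel, in
#'   (0, 1].
#' @param rescale_factor spatial rescale applied to the overlay before blur
#'   and crop (1 = render the working grid 1:1).
#' @param seed integer seed controlling all randomness, or `NULL` to use the
#'   caller's RNG stream.
#' @return a validated list of class `upaint_sim_config`.
#' @export
sim_config <- function(field_width = 512L, n_trajectories = 10L,
                       n_frames = 500L, step_length = 0.5,
                       heading_noise_sd = 0.35, gt_blur_sd = 1.25,
                       wf_blur_sd = 20, wf_small_size = 32L,
                       tile_size = 256L, sparse_fraction = 0.1,
                       rescale_factor = 1, seed = NULL) {
  cfg <- list(field_width = as.integer(field_width),
              n_trajectories = as.integer(n_trajectories),
              n_frames = as.integer(n_frames),
              step_length = step_length,
              heading_noise_sd = heading_noise_sd,
              gt_blur_sd = gt_blur_sd, wf_blur_sd = wf_blur_sd,
              wf_small_size = as.integer(wf_small_size),
              tile_size = as.integer(tile_size),
              sparse_fraction = sparse_fraction,
              rescale_factor = rescale_factor,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  problems <- character()
  pos <- c("field_width", "n_trajectories", "n_frames", "step_length",
           "gt_blur_sd", "wf_blur_sd", "wf_small_size", "tile_size",
           "rescale_factor")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      problems <- c(problems, sprintf("'%s' must be a single positive number", f))
  if (!is.numeric(cfg$heading_noise_sd) || cfg$heading_noise_sd < 0)
    problems <- c(problems, "'heading_noise_sd' must be >= 0")
  if (!is.numeric(cfg$sparse_fraction) || cfg$sparse_fraction <= 0 ||
      cfg$sparse_fraction > 1)
    problems <- c(problems, "'sparse_fraction' must lie in (0, 1]")
  if (length(problems) == 0L && cfg$tile_size %% cfg$wf_small_size != 0L)
    problems <- c(problems, "'wf_small_size' must divide 'tile_size'")
  if (length(problems) == 0L &&
      round(cfg$field_width * cfg$rescale_factor) < cfg$tile_size)
    problems <- c(problems,
                  "field_width * rescale_factor must be at least tile_size")
  if (length(problems))
    stop("invalid simulation configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "upaint_sim_config")
}

#' Simulate filament trajectories
#'
#' Each trajectory starts at a uniformly random point on the field boundary
#' and takes `n_frames - 1` steps of exactly `step_length` pixels; the step
#' heading is the direction toward the field center plus a
#' `N(0, heading_noise_sd^2)` angle. Points may leave the field; the renderer
#' clips them.
#'
#' @param config an [sim_config()] object.
#' @param seed overriding seed (defaults to `config$seed`).
#' @return an object of class `upaint_trajectories`: a list with `points`
#'   (one `n_frames` x 3 matrix per trajectory, columns `frame`, `x`, `y`;
#'   `frame` is 0-based), `field_width`, `step_length` and `n_frames`.
#' @export
simulate_trajectories <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "upaint_sim_config"))
  fw <- config$field_width
  nt <- config$n_trajectories
  nf <- config$n_frames
  with_seed(seed, {
    side <- sample.int(4L, nt, replace = TRUE)
    off <- runif(nt, 0, fw)
    x <- ifelse(side == 1L, 0, ifelse(side == 2L, fw, off))
    y <- ifelse(side == 3L, 0, ifelse(side == 4L, fw, off))
    cx <- fw / 2
    xs <- matrix(0, nf, nt)
    ys <- matrix(0, nf, nt)
    xs[1L, ] <- x
    ys[1L, ] <- y
    if (nf > 1L) {
      for (f in 2:nf) {
        theta <- atan2(cx - y, cx - x) +
          rnorm(nt, 0, config$heading_noise_sd)
        x <- x + config$step_length * cos(theta)
        y <- y + config$step_length * sin(theta)
        xs[f, ] <- x
        ys[f, ] <- y
      }
    }
    pts <- lapply(seq_len(nt), function(k)
      cbind(frame = 0:(nf - 1L), x = xs[, k], y = ys[, k]))
    structure(list(points = pts, field_width = fw,
                   step_length = config$step_length, n_frames = nf),
              class = "upaint_trajectories")
  })
}

#' @export
print.upaint_trajectories <- function(x, ...) {
  cat(sprintf("<upaint_trajectories> %d trajectories x %d frames, field %d px\n",
              length(x$points), x$n_frames, x$field_width))
  invisible(x)
}

#' Overlay trajectory points from selected frames into a count image
#'
#' Each in-field point of a selected frame adds one count to its containing
#' pixel; pixel (i, j) (0-based) covers \[i, i+1) x \[j, j+1) (floor
#' binning). The total equals the number of in-field selected points.
#'
#' @param traj an `upaint_trajectories` object.
#' @param frames integer vector of 0-based frame indices, or `NULL` for all
#'   frames. An empty vector yields an all-zero image.
#' @return an `upaint_image` of kind "overlay", `field_width` square counts
#'   (row = y, column = x).
#' @export
overlay_frames <- function(traj, frames = NULL) {
  stopifnot(inherits(traj, "upaint_trajectories"))
  fw <- traj$field_width
  if (is.null(frames)) frames <- 0:(traj$n_frames - 1L)
  if (length(frames) &&
      (min(frames) < 0L || max(frames) >= traj$n_frames))
    stop("frame indices must lie in [0, n_frames)")
  counts <- numeric(fw * fw)
  if (length(frames)) {
    keep_frame <- logical(traj$n_frames)
    keep_frame[frames + 1L] <- TRUE
    for (p in traj$points) {
      sel <- keep_frame[p[, "frame"] + 1L]
      xx <- p[sel, "x"]
      yy <- p[sel, "y"]
      inf <- xx >= 0 & xx < fw & yy >= 0 & yy < fw
      if (any(inf)) {
        cell <- floor(yy[inf]) + fw * floor(xx[inf]) + 1
        counts <- counts + tabulate(cell, nbins = fw * fw)
      }
    }
  }
  upaint_image(matrix(counts, fw, fw), kind = "overlay")
}

# rescale -> blur -> center-crop chain shared by ground-truth and sparse
# renders.
.render_overlay <- function(overlay, config, kind) {
  m <- as_matrix(overlay)
  if (config$rescale_factor != 1) {
    n_out <- round(nrow(m) * config$rescale_factor)
    # preserve total counts under rescale
    m <- resize_bilinear(m, n_out) * (sum(m) / max(1e-12, sum(resize_bilinear(m, n_out))))
  }
  if (nrow(m) < config$tile_size)
    stop("overlay (", nrow(m), " px) is smaller than tile_size (",
         config$tile_size, ") after rescale")
  m <- gaussian_blur(m, config$gt_blur_sd)
  o <- (nrow(m) - config$tile_size) %/% 2L
  m <- m[(o + 1L):(o + config$tile_size), (o + 1L):(o + config$tile_size)]
  upaint_image(m, kind = kind)
}

#' Render the dense ground-truth image from an all-frame overlay
#'
#' Applies the rescale / Gaussian blur (sigma `gt_blur_sd`) / center-crop
#' chain, yielding a `tile_size` square nonnegative intensity image.
#' @param overlay output of [overlay_frames()] over all frames.
#' @inheritParams simulate_trajectories
#' @return an `upaint_image` of kind "ground_truth".
#' @export
make_ground_truth <- function(overlay, config) {
  stopifnot(inherits(config, "upaint_sim_config"))
  .render_overlay(overlay, config, "ground_truth")
}

#' Derive the widefield channel from a ground-truth tile
#'
#' Blurs with sigma `wf_blur_sd`, area-averages down to the
#' `wf_small_size` grid (the diffraction-limited camera's sampling), and
#' bilinearly rescales back to `tile_size`, limiting the spatial frequency
#' content accordingly.
#' @param gt ground-truth tile (`upaint_image` or matrix, `tile_size`
#'   square).
#' @inheritParams simulate_trajectories
#' @return an `upaint_image` of kind "widefield".
#' @export
make_widefield <- function(gt, config) {
  stopifnot(inherits(config, "upaint_sim_config"))
  m <- as_matrix(gt)
  stopifnot(nrow(m) == config$tile_size, ncol(m) == config$tile_size)
  m <- gaussian_blur(m, config$wf_blur_sd)
  m <- downsample_mean(m, config$tile_size %/% config$wf_small_size)
  m <- upsample_bilinear(m, config$tile_size)
  upaint_image(m, kind = "widefield")
}

# round-half-up sparse frame count
.sparse_n <- function(config) {
  x <- config$sparse_fraction * config$n_frames
  if (x < 1)
    stop("sparse_fraction * n_frames is below 1; no frame can be selected")
  floor(x + 0.5)
}

#' Render the sparse channel from a frame subset
#'
#' Selects `round(sparse_fraction * n_frames)` frames — uniformly at random
#' (`mode = "random"`, the simulation convention) or the first ones
#' (`mode = "first"`, the real-acquisition convention) — and applies the same
#' overlay/blur/crop chain as [make_ground_truth()].
#' @param traj an `upaint_trajectories` object.
#' @inheritParams simulate_trajectories
#' @param mode `"random"` or `"first"`.
#' @return an `upaint_image` of kind "sparse" with the chosen frames in
#'   `attr(, "frames")`.
#' @export
make_sparse <- function(traj, config, mode = c("random", "first"),
                        seed = NULL) {
  stopifnot(inherits(config, "upaint_sim_config"))
  mode <- match.arg(mode)
  n <- .sparse_n(config)
  frames <- if (mode == "first") 0:(n - 1L)
            else with_seed(seed, sort(sample.int(config$n_frames, n) - 1L))
  img <- .render_overlay(overlay_frames(traj, frames), config, "sparse")
  attr(img, "frames") <- frames
  img
}

#' Generate aligned (widefield, sparse, dense) training triplets
#'
#' Simulates `n_sets` independent fields; for each, the same trajectories
#' underlie all three channels. Sparse and dense renders are normalized by
#' the dense maximum (preserving the physical subset intensity relation);
#' the widefield channel is normalized to its own maximum. Deterministic
#' given `seed`.
#' @inheritParams simulate_trajectories
#' @param n_sets number of triplets.
#' @param sparse_mode frame-selection mode for the sparse channel.
#' @return a list of `upaint_triplet` objects (see [upaint_triplet()]).
#' @export
generate_dataset <- function(config, n_sets, seed = config$seed,
                             sparse_mode = "random") {
  stopifnot(inherits(config, "upaint_sim_config"), n_sets >= 1)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      traj <- simulate_trajectories(config, seed = NULL)
      gt <- make_ground_truth(overlay_frames(traj), config)
      wf <- make_widefield(gt, config)
      sp <- make_sparse(traj, config, mode = sparse_mode, seed = NULL)
      dmax <- max(gt$data)
      wmax <- max(wf$data)
      upaint_triplet(
        widefield = if (wmax > 0) wf$data / wmax else wf$data,
        sparse = if (dmax > 0) pmin(sp$data / dmax, 1) else sp$data,
        dense = if (dmax > 0) gt$data / dmax else gt$data,
        grid_index = c(0L, 0L),
        source_id = sprintf("sim%04d", i))
    })
  })
}

#' Write triplets to disk as 16-bit TIFFs with a JSON sidecar
#'
#' One file per channel (`_wf`, `_sparse`, `_gt` suffixes) plus one JSON
#' sidecar per triplet recording source, grid index and, when given, the full
#' simulation configuration and seed.
#' @param triplets list of `upaint_triplet`.
#' @param dir output directory (created if missing).
#' @param config optional [sim_config()] echoed into the sidecars.
#' @return data.frame manifest of written files, invisibly.
#' @export
write_triplets <- function(triplets, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(triplets), function(i) {
    tp <- triplets[[i]]
    base <- file.path(dir, sprintf("%s_r%dc%d", tp$source_id,
                                   tp$grid_index[1], tp$grid_index[2]))
    paths <- paste0(base, c("_wf.tif", "_sparse.tif", "_gt.tif"))
    write_image(tp$widefield, paths[1])
    write_image(tp$sparse, paths[2])
    write_image(tp$dense, paths[3])
    sidecar <- paste0(base, ".json")
    jsonlite::write_json(
      list(source_id = tp$source_id, grid_index = tp$grid_index,
           files = list(widefield = basename(paths[1]),
                        sparse = basename(paths[2]),
                        dense = basename(paths[3])),
           config = if (is.null(config)) NULL else unclass(config)),
      sidecar, auto_unbox = TRUE, digits = NA, null = "null")
    data.frame(source_id = tp$source_id,
               widefield = paths[1], sparse = paths[2], dense = paths[3],
               sidecar = sidecar, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}
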