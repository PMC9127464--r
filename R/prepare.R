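# Dataset preparation: cut full fields into 256x256 tiles, drop low-content
# tiles by comparing tile means with the whole-image mean, normalize to the
# uncut maximum, and zip the channels into aligned training triplets.

#' Aligned training triplet
#'
#' One spatial tile of the widefield, sparse and dense (ground-truth)
#' channels, normalized to \[0, 1\], sharing a grid position within a source
#' field.
#' @param widefield,sparse,dense numeric matrices of identical size with
#'   values in \[0, 1\].
#' @param grid_index integer `(row, col)` of the tile in its source field
#'   (0-based).
#' @param source_id identifier of the uncut field the tile came from.
#' @return an object of class `upaint_triplet`.
#' @export
upaint_triplet <- function(widefield, sparse, dense,
                           grid_index = c(0L, 0L), source_id = "field") {
  for (ch in list(widefield, sparse, dense)) {
    stopifnot(is.matrix(ch))
    if (min(ch) < -1e-9 || max(ch) > 1 + 1e-9)
      stop("triplet intensities must lie in [0, 1]; normalize first")
  }
  stopifnot(all(dim(widefield) == dim(sparse)),
            all(dim(sparse) == dim(dense)))
  structure(list(widefield = widefield, sparse = sparse, dense = dense,
                 grid_index = as.integer(grid_index),
                 source_id = source_id),
            class = "upaint_triplet")
}

#' @export
print.upaint_triplet <- function(x, ...) {
  cat(sprintf("<upaint_triplet> %s (%d,%d), %d x %d px\n", x$source_id,
              x$grid_index[1], x$grid_index[2],
              nrow(x$dense), ncol(x$dense)))
  invisible(x)
}

#' Cut an image into non-overlapping tiles
#'
#' Tiles follow a regular `tile_size` grid in row-major order; trailing
#' partial tiles are discarded.
#' @param image matrix or `upaint_image`, at least `tile_size` in both
#'   dimensions.
#' @param tile_size tile width in pixels.
#' @return a list of `list(grid_index = c(row, col), tile = matrix)` with
#'   0-based grid indices.
#' @export
tile_image <- function(image, tile_size = 256L) {
  m <- as_matrix(image)
  if (nrow(m) < tile_size || ncol(m) < tile_size)
    stop("image (", nrow(m), "x", ncol(m), ") is smaller than tile_size (",
         tile_size, ")")
  nr <- nrow(m) %/% tile_size
  nc <- ncol(m) %/% tile_size
  out <- vector("list", nr * nc)
  k <- 1L
  for (r in seq_len(nr) - 1L) {
    for (cc in seq_len(nc) - 1L) {
      out[[k]] <- list(
        grid_index = c(r, cc),
        tile = m[(r * tile_size + 1L):((r + 1L) * tile_size),
                 (cc * tile_size + 1L):((cc + 1L) * tile_size)])
      k <- k + 1L
    }
  }
  out
}

#' Keep tiles whose mean intensity reaches a fraction of the whole-image mean
#'
#' A tile is kept iff `mean(tile) >= alpha * whole_image_mean`; tiles with
#' low mean intensity (little structure) are excluded.
#' @param tiles output of [tile_image()].
#' @param whole_image_mean mean intensity of the *uncut* image.
#' @param alpha threshold multiplier (default 1; 0 keeps everything).
#' @return the kept tiles, with the logical keep mask in `attr(, "mask")`.
#' @export
filter_tiles <- function(tiles, whole_image_mean, alpha = 1) {
  mask <- vapply(tiles, function(t) mean(t$tile) >= alpha * whole_image_mean,
                 logical(1))
  structure(tiles[mask], mask = mask)
}

#' Normalize intensities by the uncut-image maximum
#'
#' Divides every pixel by `uncut_max` so the brightest pixel of the uncut
#' field maps to exactly 1. Channels are normalized independently, each by
#' its own uncut maximum.
#' @param x a matrix, `upaint_image`, or list of tiles from [tile_image()].
#' @param uncut_max maximum intensity of the corresponding uncut image
#'   (must be > 0).
#' @return same shape as `x`, intensities in \[0, 1\].
#' @export
normalize_channel <- function(x, uncut_max) {
  if (!is.numeric(uncut_max) || uncut_max <= 0)
    stop("'uncut_max' must be positive (blank field?)")
  if (is.list(x) && !inherits(x, "upaint_image"))
    lapply(x, function(t) { t$tile <- t$tile / uncut_max; t })
  else as_matrix(x) / uncut_max
}

#' Assemble aligned training triplets from three full fields
#'
#' The three fields must be pixel-aligned and equally sized (upsample the
#' widefield to render scale first). Each is tiled; the keep mask is derived
#' from the dense (ground-truth) channel via [filter_tiles()] and applied to
#' all channels; each channel is normalized by its own uncut maximum; tiles
#' are zipped by grid index.
#' @param wf_field,sparse_field,dense_field matrices or `upaint_image`s of
#'   identical size.
#' @param tile_size tile width (default 256).
#' @param alpha exclusion threshold multiplier, see [filter_tiles()].
#' @param source_id identifier recorded on every emitted triplet.
#' @return a list of `upaint_triplet`.
#' @export
assemble_triplets <- function(wf_field, sparse_field, dense_field,
                              tile_size = 256L, alpha = 1,
                              source_id = "field") {
  wf <- as_matrix(wf_field)
  sp <- as_matrix(sparse_field)
  de <- as_matrix(dense_field)
  if (!all(dim(wf) == dim(sp)) || !all(dim(sp) == dim(de)))
    stop("channel fields differ in size; align and upsample first")
  for (ch in list(wf = wf, sparse = sp, dense = de))
    if (max(ch) <= 0)
      stop("a channel is entirely blank (uncut maximum is 0)")
  tiles_de <- tile_image(de, tile_size)
  mask <- attr(filter_tiles(tiles_de, mean(de), alpha), "mask")
  tiles_wf <- tile_image(wf, tile_size)[mask]
  tiles_sp <- tile_image(sp, tile_size)[mask]
  tiles_de <- tiles_de[mask]
  tiles_wf <- normalize_channel(tiles_wf, max(wf))
  tiles_sp <- normalize_channel(tiles_sp, max(sp))
  tiles_de <- normalize_channel(tiles_de, max(de))
  mapply(function(w, s, d) {
    upaint_triplet(w$tile, s$tile, d$tile, grid_index = d$grid_index,
                   source_id = source_id)
  }, tiles_wf, tiles_sp, tiles_de, SIMPLIFY = FALSE)
}

#' Split triplets into train and test sets at the source-field level
#'
#' All tiles from one source field land on the same side (no spatial
#' leakage between train and test). Deterministic under `seed`.
#' @param triplets list of `upaint_triplet`.
#' @param test_fraction fraction of source fields held out, in (0, 1).
#' @param seed seed for the draw, or `NULL` for the caller's stream.
#' @return `list(train = ..., test = ...)`.
#' @export
split_dataset <- function(triplets, test_fraction, seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  src <- vapply(triplets, function(t) t$source_id, character(1))
  ids <- unique(src)
  if (length(ids) < 2L)
    stop("need at least 2 source fields to split")
  n_test <- min(max(1L, round(test_fraction * length(ids))),
                length(ids) - 1L)
  test_ids <- with_seed(seed, ids[sample.int(length(ids), n_test)])
  list(train = triplets[!(src %in% test_ids)],
       test = triplets[src %in% test_ids])
}

#' Reassemble a full field from grid-indexed tiles
#'
#' Inverse of [tile_image()] on the covered region; the tiles must cover a
#' complete rectangular grid.
#' @param tiles list of `list(grid_index = c(row, col), tile = matrix)`.
#' @return the stitched matrix.
#' @export
stitch_tiles <- function(tiles) {
  stopifnot(length(tiles) >= 1)
  gi <- t(vapply(tiles, function(t) as.integer(t$grid_index), integer(2)))
  ts <- nrow(tiles[[1]]$tile)
  nr <- max(gi[, 1]) + 1L
  nc <- max(gi[, 2]) + 1L
  want <- paste(rep(seq_len(nr) - 1L, each = nc),
                rep(seq_len(nc) - 1L, times = nr))
  have <- paste(gi[, 1], gi[, 2])
  gaps <- setdiff(want, have)
  if (length(gaps))
    stop("incomplete tile grid; missing cell(s): ",
         paste0("(", sub(" ", ",", gaps), ")", collapse = ", "))
  out <- matrix(0, nr * ts, nc * ts)
  for (t in tiles) {
    r <- t$grid_index[1]
    cc <- t$grid_index[2]
    out[(r * ts + 1L):((r + 1L) * ts),
        (cc * ts + 1L):((cc + 1L) * ts)] <- t$tile
  }
  out
}
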