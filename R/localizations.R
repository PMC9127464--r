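# Single-molecule localization tables: reading (Picasso-dialect HDF5 or
# headered CSV), PSF-ellipticity quality filtering, frame subsetting, and
# oversampled histogram rendering.

.required_cols <- c("frame", "x", "y")

#' Ellipticity of a fitted PSF from its widths
#'
#' `1 - min(sx, sy) / max(sx, sy)`, dimensionless in \[0, 1). Other
#' conventions exist; pre-compute an `ellipticity` column if yours differs.
#' @param sx,sy fitted PSF widths (camera pixels).
#' @return numeric vector.
#' @export
ellipticity_from_widths <- function(sx, sy) {
  1 - pmin(sx, sy) / pmax(sx, sy)
}

#' Read a localization table
#'
#' Reads Picasso-style fit output: a headered CSV or an HDF5 file holding a
#' `locs` table (the Picasso dialect). HDF5 ingestion shells out to the
#' system `python`/h5py, converting `locs` to CSV. Requires columns
#' `frame`, `x`, `y`; optional `sx`, `sy`, `ellipticity`, `photons`. When
#' `sx`/`sy` are present and `ellipticity` is not, it is derived via
#' [ellipticity_from_widths()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"hdf5"`.
#' @return a `data.frame` with 0-based integer `frame` and numeric
#'   coordinates in camera pixels.
#' @export
read_localizations <- function(path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("h5", "hdf5"))
      "hdf5" else "csv"
  if (format == "hdf5") {
    csv <- tempfile(fileext = ".csv")
    on.exit(unlink(csv))
    py <- Sys.which("python")
    if (py == "") stop("HDF5 ingestion needs a system 'python' with h5py")
    script <- sprintf(
      "import h5py, sys, numpy as np\nf = h5py.File(%s, 'r')\nd = f['locs'][...]\ncols = d.dtype.names\nwith open(%s, 'w') as out:\n    out.write(','.join(cols) + '\\n')\n    for row in d:\n        out.write(','.join(repr(float(v)) for v in row) + '\\n')\n",
      deparse(path), deparse(csv))
    status <- system2(py, "-", input = script, stdout = FALSE, stderr = "")
    if (status != 0) stop("python/h5py failed to read ", path)
    path <- csv
  }
  if (file.size(path) == 0) {
    warning("empty localization file: returning an empty table")
    return(data.frame(frame = integer(), x = numeric(), y = numeric()))
  }
  tab <- read.csv(path)
  missing <- setdiff(.required_cols, names(tab))
  if (length(missing))
    stop("localization table is missing required column(s): ",
         paste(missing, collapse = ", "))
  tab$frame <- as.integer(tab$frame)
  if (!"ellipticity" %in% names(tab) && all(c("sx", "sy") %in% names(tab)))
    tab$ellipticity <- ellipticity_from_widths(tab$sx, tab$sy)
  tab
}

#' Write a localization table to CSV
#' @param locs localization data.frame.
#' @param path output .csv path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' Remove elongated-PSF localizations
#'
#' Keeps exactly the rows with ellipticity <= `max_ellipticity` (the quality
#' cut removes localizations *greater than* the threshold; the boundary is
#' kept), preserving row order. Ellipticity is taken from the table or
#' derived from `sx`/`sy`.
#' @param locs localization data.frame.
#' @param max_ellipticity threshold (default 0.6).
#' @return the filtered data.frame.
#' @export
filter_ellipticity <- function(locs, max_ellipticity = 0.6) {
  e <- if ("ellipticity" %in% names(locs)) locs$ellipticity
       else if (all(c("sx", "sy") %in% names(locs)))
         ellipticity_from_widths(locs$sx, locs$sy)
       else stop("no 'ellipticity' column and no 'sx'/'sy' to derive it from")
  locs[e <= max_ellipticity, , drop = FALSE]
}

#' Subset a localization table by acquisition frames
#'
#' `mode = "first"` keeps rows with `frame < n` (the sparse-input convention
#' for real acquisitions); `mode = "random"` keeps rows whose frame falls in
#' an `n`-element uniform draw from the distinct frames present.
#' @param locs localization data.frame.
#' @param n number of frames to keep.
#' @param mode `"first"` or `"random"`.
#' @param seed seed for the random draw, or `NULL` for the caller's stream.
#' @return the subsetted data.frame, original row order preserved.
#' @export
select_frames <- function(locs, n, mode = c("first", "random"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n <= 0) stop("'n' must be a positive frame count")
  if (mode == "first") {
    if (nrow(locs) && n > max(locs$frame) + 1)
      stop("'n' exceeds the number of acquisition frames")
    locs[locs$frame < n, , drop = FALSE]
  } else {
    fr <- unique(locs$frame)
    if (n > length(fr)) stop("'n' exceeds the number of distinct frames")
    keep <- with_seed(seed, fr[sample.int(length(fr), n)])
    locs[locs$frame %in% keep, , drop = FALSE]
  }
}

#' Rendering specification for localization histograms
#'
#' The target pixel size is `camera_pixel_size / oversampling`; defaults
#' give 8 nm render pixels from 128 nm camera pixels at 16x oversampling.
#' @param oversampling integer sub-pixel grid factor.
#' @param camera_pixel_size camera pixel edge in nm.
#' @param blur_mode `"none"` (plain histogram) or `"gaussian"` (blur the
#'   histogram by `blur_sd` render pixels).
#' @param blur_sd Gaussian sd in render pixels for `blur_mode = "gaussian"`.
#' @param bit_depth 8 or 16; counts are clipped to the depth's maximum.
#' @return a list of class `upaint_render_spec`.
#' @export
render_spec <- function(oversampling = 16L, camera_pixel_size = 128,
                        blur_mode = c("none", "gaussian"), blur_sd = 1,
                        bit_depth = 16L) {
  blur_mode <- match.arg(blur_mode)
  oversampling <- as.integer(oversampling)
  stopifnot(oversampling >= 1, camera_pixel_size > 0,
            bit_depth %in% c(8L, 16L))
  structure(list(oversampling = oversampling,
                 camera_pixel_size = camera_pixel_size,
                 target_pixel_size = camera_pixel_size / oversampling,
                 blur_mode = blur_mode, blur_sd = blur_sd,
                 bit_depth = as.integer(bit_depth)),
            class = "upaint_render_spec")
}

#' Render localizations into an oversampled histogram image
#'
#' A localization at camera coordinates (x, y) lands in render cell
#' `(floor(x * oversampling), floor(y * oversampling))`; before bit-depth
#' clipping the histogram total equals the number of rendered localizations.
#' @param locs localization data.frame.
#' @param spec a [render_spec()].
#' @param width,height field extent in camera pixels; defaults to the
#'   smallest integer extent containing all localizations.
#' @return an `upaint_image` of kind "render" (row = y), with
#'   `pixel_size = spec$target_pixel_size` nm.
#' @export
render_localizations <- function(locs, spec = render_spec(), width = NULL,
                                 height = NULL) {
  stopifnot(inherits(spec, "upaint_render_spec"))
  os <- spec$oversampling
  if (is.null(width))
    width <- if (nrow(locs)) floor(max(locs$x)) + 1L else 1L
  if (is.null(height))
    height <- if (nrow(locs)) floor(max(locs$y)) + 1L else 1L
  W <- as.integer(width) * os
  H <- as.integer(height) * os
  counts <- numeric(H * W)
  if (nrow(locs)) {
    cx <- floor(locs$x * os)
    cy <- floor(locs$y * os)
    ok <- cx >= 0 & cx < W & cy >= 0 & cy < H
    counts <- tabulate(cy[ok] + H * cx[ok] + 1, nbins = H * W)
  }
  m <- matrix(counts, H, W)
  if (spec$blur_mode == "gaussian") m <- gaussian_blur(m, spec$blur_sd)
  m <- pmin(m, 2^spec$bit_depth - 1)
  upaint_image(m, pixel_size = spec$target_pixel_size, kind = "render")
}
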