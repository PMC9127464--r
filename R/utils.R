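# Shared numeric and I/O helpers: seeded evaluation, reflective-boundary
# Gaussian blur, block-mean downsampling, bilinear upsampling, 16-bit image
# round-trips, and the lightweight image container.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state. With `seed = NULL` the expression runs on the current
#' stream unchanged.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# 1-D blur/resize operators are built as dense matrices so a 2-D separable
# pass is two GEMMs: K_rows %*% X %*% t(K_cols).

# Reflective (mirror-about-edge) index into 1..n.
.reflect_index <- function(i, n) {
  # period 2n reflection: maps any integer into 1..n
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

.gauss_kernel <- function(sd) {
  r <- max(1L, ceiling(4 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k / sum(k)
}

.blur_matrix <- function(n, sd) {
  k <- .gauss_kernel(sd)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (t in seq_along(k)) {
    src <- .reflect_index(seq_len(n) + (t - 1L - r), n)
    idx <- cbind(seq_len(n), src)
    K[idx] <- K[idx] + k[t]
  }
  K
}

#' Gaussian blur with reflective boundary handling
#'
#' Separable Gaussian filter (kernel radius 4 sd) with mirror padding, so a
#' constant field stays constant and cropped tiles show no dark rim.
#' @param x numeric matrix.
#' @param sd kernel standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(x, sd) {
  x <- as_matrix(x)
  stopifnot(is.numeric(sd), sd >= 0)
  if (sd == 0) return(x)
  Kr <- .blur_matrix(nrow(x), sd)
  Kc <- if (ncol(x) == nrow(x)) Kr else .blur_matrix(ncol(x), sd)
  Kr %*% x %*% t(Kc)
}

# Block-mean downsample by an integer factor (area average, the integration a
# camera pixel performs).
downsample_mean <- function(x, factor) {
  x <- as_matrix(x)
  stopifnot(nrow(x) %% factor == 0, ncol(x) %% factor == 0)
  gi <- rep(seq_len(nrow(x) / factor), each = factor)
  gj <- rep(seq_len(ncol(x) / factor), each = factor)
  t(rowsum(t(rowsum(x, gi)), gj)) / factor^2
}

# Bilinear 1-D interpolation matrix from n_in samples to n_out (pixel-center
# alignment).
.bilinear_matrix <- function(n_out, n_in) {
  U <- matrix(0, n_out, n_in)
  s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  i0 <- pmin(pmax(floor(s), 1), n_in)
  w <- pmin(pmax(s - i0, 0), 1)
  i1 <- pmin(i0 + 1, n_in)
  U[cbind(seq_len(n_out), i0)] <- U[cbind(seq_len(n_out), i0)] + (1 - w)
  U[cbind(seq_len(n_out), i1)] <- U[cbind(seq_len(n_out), i1)] + w
  U
}

upsample_bilinear <- function(x, n_out) {
  x <- as_matrix(x)
  Ur <- .bilinear_matrix(n_out, nrow(x))
  Uc <- if (ncol(x) == nrow(x)) Ur else .bilinear_matrix(n_out, ncol(x))
  Ur %*% x %*% t(Uc)
}

resize_bilinear <- upsample_bilinear

#' Rendered image container
#'
#' A thin wrapper around a numeric intensity matrix recording the render
#' pixel size and the image's role in the workflow.
#' @param data numeric matrix, row = y, column = x.
#' @param pixel_size pixel edge length in nm (`NA` for simulation pixels).
#' @param kind one of "overlay", "ground_truth", "widefield", "sparse",
#'   "render", "reconstruction".
#' @return an object of class `upaint_image`.
#' @export
upaint_image <- function(data, pixel_size = NA_real_, kind = "render") {
  stopifnot(is.matrix(data), is.numeric(data))
  structure(list(data = data, pixel_size = pixel_size, kind = kind),
            class = "upaint_image")
}

#' @export
print.upaint_image <- function(x, ...) {
  cat(sprintf("<upaint_image> %s, %d x %d px, pixel size %s nm, range [%g, %g]\n",
              x$kind, nrow(x$data), ncol(x$data),
              ifelse(is.na(x$pixel_size), "?", format(x$pixel_size)),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Extract the intensity matrix from an image or pass a matrix through
#' @param x `upaint_image` or numeric matrix.
#' @return numeric matrix.
#' @export
as_matrix <- function(x) {
  if (inherits(x, "upaint_image")) x$data
  else if (is.matrix(x)) x
  else stop("expected an upaint_image or a numeric matrix")
}

#' Write a grayscale image to TIFF (16-bit) or PNG (8-bit)
#'
#' Values must already lie in \[0, 1\]; the format is chosen from the file
#' extension. PNG export quantizes to 8 bits, matching the 8-bit render
#' convention; TIFF keeps 16 bits.
#' @param x matrix or `upaint_image` with values in \[0, 1\].
#' @param path output file ending in .tif/.tiff or .png.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  m <- as_matrix(x)
  if (min(m) < 0 || max(m) > 1)
    stop("image values must be in [0, 1] before writing; normalize first")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read a grayscale TIFF/PNG image as a matrix scaled to \[0, 1\]
#' @param path image file.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported image extension: ", ext)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
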