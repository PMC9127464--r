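# U-Net construction, training and inference. The network is a classic
# encoder-decoder with skip connections: two 3x3 same-padded ReLU
# convolutions per stage, 2x2 max-pooling on the way down, 2x2 stride-2
# transposed convolutions on the way up, channel concatenation at matching
# resolutions, and a linear 1x1 output convolution. At the defaults
# (depth 4, base 64) this instantiates slightly more than 31 million
# trainable parameters. The numerical backend (single-precision im2col +
# GEMM with Adam) lives in src/unet.cpp.

#' U-Net architecture specification
#'
#' Counting the input stage, the downsampling and upsampling convolutional
#' stages, and the output stage the default network has 10 layers
#' (4 down + 4 up + input + output).
#' @param in_channels 1 (sparse-only or widefield-only input) or 2
#'   (widefield + sparse concatenated).
#' @param out_channels must be 1 (the dense reconstruction).
#' @param depth number of downsampling stages (default 4).
#' @param base_channels feature maps at the first stage (default 64,
#'   doubling per stage).
#' @param tile_size expected tile width; must be divisible by `2^depth`.
#' @return a list of class `upaint_unet_spec`.
#' @export
unet_spec <- function(in_channels = 1L, out_channels = 1L, depth = 4L,
                      base_channels = 64L, tile_size = 256L) {
  stopifnot(in_channels >= 1, out_channels == 1L, depth >= 1,
            base_channels >= 1)
  if (tile_size %% 2^depth != 0)
    stop("tile_size (", tile_size, ") must be divisible by 2^depth (",
         2^depth, ")")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = 1L, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 tile_size = as.integer(tile_size)),
            class = "upaint_unet_spec")
}

# Layer shape table mirroring the backend's construction order exactly:
# enc stages (2 convs each), bottleneck (2 convs), dec stages (tconv + 2
# convs, deepest first), 1x1 output conv.
unet_layer_shapes <- function(spec) {
  d <- spec$depth
  b <- spec$base_channels
  shapes <- list()
  add <- function(name, type, inC, outC) {
    wr <- if (type == "conv3") inC * 9L else inC
    wc <- if (type == "tconv") 4L * outC else outC
    fan <- if (type == "conv3") inC * 9L else inC
    shapes[[length(shapes) + 1L]] <<- list(name = name, type = type,
                                           inC = inC, outC = outC,
                                           dim_W = c(wr, wc), n_bias = outC,
                                           fan_in = fan)
  }
  prev <- spec$in_channels
  for (s in seq_len(d)) {
    ch <- b * 2L^(s - 1L)
    add(sprintf("enc%d_1", s), "conv3", prev, ch)
    add(sprintf("enc%d_2", s), "conv3", ch, ch)
    prev <- ch
  }
  ch <- b * 2L^d
  add("bottleneck_1", "conv3", prev, ch)
  add("bottleneck_2", "conv3", ch, ch)
  for (s in rev(seq_len(d))) {
    cs <- b * 2L^(s - 1L)
    add(sprintf("up%d", s), "tconv", cs * 2L, cs)
    add(sprintf("dec%d_1", s), "conv3", cs * 2L, cs)
    add(sprintf("dec%d_2", s), "conv3", cs, cs)
  }
  add("out", "conv1", b, 1L)
  shapes
}

#' Build a U-Net model
#'
#' Initializes weights (He-normal for the ReLU convolutions, Xavier for the
#' linear output) under `seed` and returns an R-side model object; the
#' compiled backend is attached lazily on first use.
#' @param spec a [unet_spec()].
#' @param seed integer seed for weight initialization, or `NULL` for the
#'   caller's RNG stream.
#' @return an object of class `upaint_unet`.
#' @export
build_network <- function(spec = unet_spec(), seed = NULL) {
  stopifnot(inherits(spec, "upaint_unet_spec"))
  shapes <- unet_layer_shapes(spec)
  weights <- with_seed(seed, lapply(shapes, function(s) {
    sdw <- if (s$type == "conv1") sqrt(1 / s$fan_in) else sqrt(2 / s$fan_in)
    list(W = matrix(rnorm(prod(s$dim_W), 0, sdw), s$dim_W[1], s$dim_W[2]),
         b = numeric(s$n_bias))
  }))
  names(weights) <- vapply(shapes, `[[`, character(1), "name")
  structure(list(spec = spec, weights = weights, frozen = FALSE,
                 backend = new.env(parent = emptyenv())),
            class = "upaint_unet")
}

# backend pointer, recreated transparently after serialization
.unet_ptr <- function(model, sync = TRUE) {
  be <- model$backend
  if (is.null(be$ptr) || !unet_ptr_valid(be$ptr)) {
    be$ptr <- unet_create_ptr(model$spec$in_channels, model$spec$depth,
                              model$spec$base_channels)
    unet_set_weights_ptr(be$ptr, unname(model$weights))
  } else if (sync) {
    unet_set_weights_ptr(be$ptr, unname(model$weights))
  }
  be$ptr
}

#' Count trainable parameters
#'
#' Works on a spec (analytic layer-by-layer sum) or a built model (sum of
#' weight and bias lengths); a frozen model reports 0 trainable parameters.
#' @param x a `upaint_unet` model or `upaint_unet_spec`.
#' @return parameter count (double to avoid integer overflow).
#' @export
count_parameters <- function(x) {
  if (inherits(x, "upaint_unet_spec"))
    return(sum(vapply(unet_layer_shapes(x),
                      function(s) prod(s$dim_W) + s$n_bias, numeric(1))))
  stopifnot(inherits(x, "upaint_unet"))
  if (isTRUE(x$frozen)) return(0)
  sum(vapply(x$weights, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Freeze a model (no trainable parameters)
#' @param model a `upaint_unet`.
#' @return the model with `frozen = TRUE`.
#' @export
freeze_network <- function(model) {
  model$frozen <- TRUE
  model
}

#' @export
print.upaint_unet <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<upaint_unet> in=%d, depth=%d, base=%d ",
                     "(%d down + %d up + input + output = %d layers), ",
                     "%s parameters%s\n"),
              s$in_channels, s$depth, s$base_channels, s$depth, s$depth,
              2L * s$depth + 2L,
              format(sum(vapply(x$weights,
                                function(l) length(l$W) + length(l$b),
                                numeric(1))), big.mark = ","),
              if (isTRUE(x$frozen)) " (frozen)" else ""))
  invisible(x)
}

#' Training configuration
#'
#' The reference schedule trains each model for 2,000 epochs on real
#' triplets, then 2,000 more on simulated triplets, then a 500-epoch real
#' fine-tune; see [paper_protocol()].
#' @param epochs number of passes over the training triplets (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param loss_name only `"mse"` (matching the PSNR/RMSE evaluation scale).
#' @param seed seed for shuffling (and any weight init done downstream).
#' @param checkpoint_every write a checkpoint every this many epochs
#'   (`Inf` = only implicit final state).
#' @return a list of class `upaint_train_config`.
#' @export
train_config <- function(epochs = 2000L, batch_size = 4L,
                         learning_rate = 1e-4, loss_name = "mse",
                         seed = 1L, checkpoint_every = Inf) {
  if (!is.numeric(epochs) || epochs < 1)
    stop("'epochs' must be at least 1")
  stopifnot(learning_rate > 0, batch_size >= 1, loss_name == "mse")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss_name = loss_name,
                 seed = as.integer(seed),
                 checkpoint_every = checkpoint_every),
            class = "upaint_train_config")
}

# Stack triplets into the (H, W, C, B) input array for a variant and the
# (H, W, 1, B) dense target.
.assemble_io <- function(triplets, variant, in_channels) {
  need <- switch(variant, "3000" = "sparse", "WF" = "widefield",
                 "WF+3000" = c("widefield", "sparse"))
  if (length(need) != in_channels)
    stop("variant '", variant, "' needs ", length(need),
         " input channel(s) but the network has ", in_channels)
  ts <- dim(triplets[[1]]$dense)
  B <- length(triplets)
  X <- array(0, c(ts[1], ts[2], in_channels, B))
  Y <- array(0, c(ts[1], ts[2], 1L, B))
  for (b in seq_len(B)) {
    tp <- triplets[[b]]
    for (k in seq_along(need)) {
      ch <- tp[[need[k]]]
      if (is.null(ch)) stop("triplet ", b, " lacks channel '", need[k], "'")
      X[, , k, b] <- ch
    }
    Y[, , 1L, b] <- tp$dense
  }
  list(X = X, Y = Y)
}

#' Train a U-Net on training triplets
#'
#' `variant` selects the input assembly: `"3000"` feeds the sparse render
#' alone, `"WF"` the widefield alone, `"WF+3000"` both as a 2-channel input
#' (widefield first). The target is always the dense channel. Loss is mean
#' squared error on \[0, 1\] intensities, optimized with Adam. Runs are
#' deterministic given the config seed and fixed thread settings
#' (best-effort: single-threaded BLAS).
#' @param model a `upaint_unet` from [build_network()].
#' @param triplets list of `upaint_triplet`, intensities in \[0, 1\].
#' @param config a [train_config()].
#' @param variant `"3000"`, `"WF"` or `"WF+3000"`.
#' @param checkpoint_dir directory for periodic checkpoints (optional).
#' @return `list(model = trained model, history = per-epoch mean MSE)`.
#' @export
train_network <- function(model, triplets, config = train_config(),
                          variant = c("3000", "WF", "WF+3000"),
                          checkpoint_dir = NULL) {
  stopifnot(inherits(model, "upaint_unet"),
            inherits(config, "upaint_train_config"))
  if (isTRUE(model$frozen)) stop("model is frozen; thaw before training")
  stopifnot(length(triplets) >= 1)
  variant <- match.arg(variant)
  io <- .assemble_io(triplets, variant, model$spec$in_channels)
  if (dim(io$X)[1] %% 2^model$spec$depth != 0)
    stop("tile size must be divisible by 2^depth")
  ptr <- .unet_ptr(model)
  ck <- config$checkpoint_every
  chunks <- if (is.finite(ck) && !is.null(checkpoint_dir)) {
    n <- config$epochs %/% ck
    c(rep(ck, n), config$epochs - n * ck)
  } else config$epochs
  chunks <- chunks[chunks > 0]
  history <- numeric(0)
  done <- 0L
  for (ch in chunks) {
    h <- unet_fit_ptr(ptr, io$X, io$Y, as.integer(ch), config$batch_size,
                      config$learning_rate, 0.9, 0.999, 1e-8,
                      config$seed + done)
    history <- c(history, h)
    done <- done + as.integer(ch)
    if (!is.null(checkpoint_dir) && done < config$epochs) {
      model$weights <- .weights_from_ptr(model, ptr)
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("epoch%05d.rds", done)),
                      config = config)
    }
  }
  model$weights <- .weights_from_ptr(model, ptr)
  list(model = model, history = history)
}

.weights_from_ptr <- function(model, ptr) {
  w <- unet_get_weights_ptr(ptr)
  names(w) <- names(model$weights)
  w
}

#' Reconstruct a dense tile from sparse and/or widefield inputs
#'
#' Inputs must match the model's channel count (`"WF+3000"` models take
#' both, widefield first) and lie in \[0, 1\]; the output is a
#' single-channel tile of the same size, clamped to \[0, 1\].
#' @param object a trained `upaint_unet`.
#' @param sparse sparse render tile (matrix or `upaint_image`), or `NULL`.
#' @param widefield widefield tile, or `NULL`.
#' @param ... unused.
#' @return reconstruction matrix in \[0, 1\].
#' @export
predict.upaint_unet <- function(object, sparse = NULL, widefield = NULL,
                                ...) {
  chans <- Filter(Negate(is.null),
                  list(widefield = if (is.null(widefield)) NULL
                                   else as_matrix(widefield),
                       sparse = if (is.null(sparse)) NULL
                                else as_matrix(sparse)))
  if (length(chans) != object$spec$in_channels)
    stop("model expects ", object$spec$in_channels, " input channel(s); ",
         length(chans), " given")
  for (ch in chans) {
    if (!all(dim(ch) == dim(chans[[1]])))
      stop("input channels differ in size")
    if (min(ch) < -1e-6 || max(ch) > 1 + 1e-6)
      stop("inputs must be normalized to [0, 1]")
  }
  h <- nrow(chans[[1]])
  w <- ncol(chans[[1]])
  if (h %% 2^object$spec$depth != 0 || w %% 2^object$spec$depth != 0)
    stop("tile size must be divisible by 2^depth")
  X <- array(0, c(h, w, length(chans), 1L))
  for (k in seq_along(chans)) X[, , k, 1L] <- chans[[k]]
  Y <- unet_forward_ptr(.unet_ptr(object), X)
  pmin(pmax(Y[, , 1L, 1L], 0), 1)
}

#' Save / load a model checkpoint
#'
#' A single serialized weights file plus a JSON sidecar recording the
#' architecture spec (and training config when given), so inference never
#' needs training-time guesswork.
#' @param model a `upaint_unet`.
#' @param path checkpoint path (.rds); the sidecar is `path` + ".json".
#' @param config optional [train_config()] echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  saveRDS(list(spec = unclass(model$spec), weights = model$weights), path)
  jsonlite::write_json(list(spec = unclass(model$spec),
                            train_config = if (is.null(config)) NULL
                                           else unclass(config),
                            n_parameters = count_parameters(model)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  spec <- do.call(unet_spec, obj$spec)
  model <- build_network(spec, seed = 0L)
  stopifnot(length(model$weights) == length(obj$weights))
  model$weights <- obj$weights
  model
}
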