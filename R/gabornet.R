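conv_out_dim <- function(H, K, S, P) (H + 2L * P - K) %/% S + 1L

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Backbone architecture of the Gabor encoder
#'
#' Three convolutional layers: a Gabor layer (128 kernels generated from 64
#' trainable parameter tuples) followed by two dense 128-channel layers, with
#' a rectifier between layers. Strides and paddings default to the unique
#' simple integer choices that map a 128x128 single-channel input to
#' 128x62x62, 128x31x31 and 128x16x16 activations (flattened final feature
#' length 32768).
#'
#' @param image_size input side length in pixels (default 128).
#' @param kernel_sizes,strides,paddings integer vectors of length 3.
#' @param channels output channels per layer (all default 128).
#' @param activation inter-layer activation, currently `"relu"`.
#' @param normalize scale images to `[0, 1]` and subtract the per-image mean
#'   before the first convolution (default `TRUE`).
#' @return object of class `backbone_spec` with a `dims` element listing each
#'   layer's `c(channels, height, width)` and `n_features`, the flattened
#'   length of the last layer.
#' @examples
#' backbone_spec(128)$dims
#' @export
backbone_spec <- function(image_size = 128L, kernel_sizes = c(9L, 3L, 3L),
                          strides = c(2L, 2L, 2L), paddings = c(2L, 1L, 1L),
                          channels = c(128L, 128L, 128L),
                          activation = "relu", normalize = TRUE) {
  stopifnot(length(kernel_sizes) == 3, length(strides) == 3,
            length(paddings) == 3, length(channels) == 3,
            image_size >= kernel_sizes[1])
  in_ch <- c(1L, channels[1L], channels[2L])
  side <- as.integer(image_size)
  dims <- vector("list", 3L)
  for (l in 1:3) {
    side <- conv_out_dim(side, kernel_sizes[l], strides[l], paddings[l])
    if (side < 1L) stop("layer ", l, " output collapses; enlarge the input")
    dims[[l]] <- c(channels[l], side, side)
  }
  structure(list(image_size = as.integer(image_size),
                 kernel_sizes = as.integer(kernel_sizes),
                 strides = as.integer(strides),
                 paddings = as.integer(paddings),
                 channels = as.integer(channels), in_channels = in_ch,
                 activation = activation, normalize = normalize,
                 dims = dims, n_features = prod(dims[[3L]])),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("Gabor encoder backbone, input", x$image_size, "x", x$image_size, "x 1\n")
  for (l in 1:3) {
    cat(sprintf("  conv%d: k=%d s=%d p=%d -> %s\n", l, x$kernel_sizes[l],
                x$strides[l], x$paddings[l],
                paste(x$dims[[l]], collapse = " x ")))
  }
  cat("  flattened feature length:", x$n_features, "\n")
  invisible(x)
}

#' Readout specification
#'
#' The map from the flattened last convolutional layer to an ROI's voxels:
#' either a single affine map (`linear`) or two affine maps with a rectifier
#' between them (`nonlinear`, the same structure as the hierarchical
#' voxel-to-voxel / feature-to-voxel readout). In nonlinear mode the latent
#' width defaults to the target voxel count.
#'
#' @param n_features input width (flattened conv3 length).
#' @param n_voxels output width (ROI voxel count).
#' @param mode `"linear"` or `"nonlinear"`.
#' @param latent latent width for nonlinear mode (default `n_voxels`).
#' @export
readout_spec <- function(n_features, n_voxels, mode = c("linear", "nonlinear"),
                         latent = NULL) {
  mode <- match.arg(mode)
  if (mode == "nonlinear" && is.null(latent)) latent <- n_voxels
  structure(list(n_features = as.integer(n_features),
                 n_voxels = as.integer(n_voxels), mode = mode,
                 latent = if (is.null(latent)) NULL else as.integer(latent)),
            class = "readout_spec")
}

init_readout <- function(spec) {
  f <- spec$n_features
  if (spec$mode == "linear") {
    list(mode = "linear",
         W = matrix(rnorm(f * spec$n_voxels, sd = sqrt(1 / f)), f, spec$n_voxels),
         b = rep(0, spec$n_voxels))
  } else {
    L <- spec$latent
    list(mode = "nonlinear",
         W1 = matrix(rnorm(f * L, sd = sqrt(2 / f)), f, L), b1 = rep(0, L),
         W2 = matrix(rnorm(L * spec$n_voxels, sd = sqrt(2 / L)), L, spec$n_voxels),
         b2 = rep(0, spec$n_voxels))
  }
}

#' Initialise Gabor encoder weights
#'
#' @param spec a [backbone_spec()].
#' @param n_voxels voxel count of the target ROI, or `NULL` for a headless
#'   (feature-only) encoder.
#' @param readout `"linear"` or `"nonlinear"`.
#' @param latent latent width for the nonlinear readout.
#' @param seed optional RNG seed for the random conv/readout initialisation.
#' @return list of class `gabornet_weights`: `gabor` ([gabor_params()]),
#'   conv biases/weights `b1`, `W2`, `b2`, `W3`, `b3`, and `readout`.
#' @export
gabornet_init <- function(spec, n_voxels = NULL,
                          readout = c("linear", "nonlinear"), latent = NULL,
                          seed = NULL) {
  readout <- match.arg(readout)
  if (!is.null(seed)) set.seed(seed)
  ch <- spec$channels; inch <- spec$in_channels; ks <- spec$kernel_sizes
  he <- function(oc, fan) matrix(rnorm(oc * fan, sd = sqrt(2 / fan)), oc, fan)
  w <- list(gabor = gabor_params(ch[1L] %/% 2L),
            b1 = rep(0, ch[1L]),
            W2 = he(ch[2L], inch[2L] * ks[2L]^2), b2 = rep(0, ch[2L]),
            W3 = he(ch[3L], inch[3L] * ks[3L]^2), b3 = rep(0, ch[3L]),
            readout = NULL)
  if (!is.null(n_voxels)) {
    w$readout <- init_readout(readout_spec(spec$n_features, n_voxels,
                                           mode = readout, latent = latent))
  }
  structure(w, class = "gabornet_weights", spec = spec)
}

# [0,1] scaling + per-image mean subtraction (configurable via spec$normalize)
prepare_stimuli <- function(X, spec) {
  if (!spec$normalize) return(X)
  rng <- range(X)
  if (rng[2] > rng[1]) X <- (X - rng[1]) / (rng[2] - rng[1])
  X - rowMeans(X)
}

as_stimulus_matrix <- function(images, spec) {
  if (is.array(images) && length(dim(images)) == 3L) {
    d <- dim(images)
    images <- matrix(images, d[1L], d[2L] * d[3L])
  }
  if (!is.matrix(images)) images <- matrix(images, nrow = 1L)
  want <- spec$image_size^2
  if (ncol(images) != want) {
    stop("stimulus side mismatch: expected ", spec$image_size, "x",
         spec$image_size, " (", want, " pixels), got ", ncol(images),
         " pixels per image")
  }
  images
}

#' Forward pass through the Gabor encoder
#'
#' @param weights a `gabornet_weights` list (see [gabornet_init()]).
#' @param images `N x side^2` matrix or `N x side x side` array of grayscale
#'   stimuli.
#' @param spec the [backbone_spec()]; defaults to the spec the weights were
#'   initialised with.
#' @param keep_pre keep pre-activation tensors (needed for backprop).
#' @return list with post-rectifier activations `conv1`, `conv2`, `conv3`
#'   (each `N x prod(dims)` in channel-major layout), `features` (alias of
#'   `conv3`, flattened), and `pred` (`N x V`) when a readout is attached.
#' @export
gabornet_forward <- function(weights, images, spec = attr(weights, "spec"),
                             keep_pre = FALSE) {
  X <- prepare_stimuli(as_stimulus_matrix(images, spec), spec)
  s <- spec$strides; p <- spec$paddings; k <- spec$kernel_sizes
  d <- spec$dims; inch <- spec$in_channels
  Wg <- gabor_bank(weights$gabor, k[1L])$weights

  z1 <- conv2d_forward_cpp(X, Wg, weights$b1, 1L, spec$image_size,
                           spec$image_size, k[1L], s[1L], p[1L])
  a1 <- relu(z1)
  z2 <- conv2d_forward_cpp(a1, weights$W2, weights$b2, inch[2L],
                           d[[1L]][2L], d[[1L]][3L], k[2L], s[2L], p[2L])
  a2 <- relu(z2)
  z3 <- conv2d_forward_cpp(a2, weights$W3, weights$b3, inch[3L],
                           d[[2L]][2L], d[[2L]][3L], k[3L], s[3L], p[3L])
  a3 <- relu(z3)

  out <- list(conv1 = a1, conv2 = a2, conv3 = a3, features = a3)
  if (!is.null(weights$readout)) {
    out$pred <- readout_forward(a3, weights$readout, spec$activation)
  }
  if (keep_pre) out$pre <- list(X = X, z1 = z1, z2 = z2, z3 = z3)
  out
}

#' Readout forward pass
#'
#' Linear mode applies one affine map; nonlinear mode applies
#' affine -> rectifier -> affine (the hierarchical-readout structure).
#'
#' @param features `N x D` feature matrix (flattened conv3 activations).
#' @param readout readout weights, as built by [gabornet_init()] or
#'   [hier_readout_init()]-style lists with `mode`, `W`/`b` or
#'   `W1`,`b1`,`W2`,`b2`.
#' @param activation activation tag for nonlinear mode (`"relu"`).
#' @return `N x V` predicted voxel matrix.
#' @export
readout_forward <- function(features, readout, activation = "relu") {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  din <- if (readout$mode == "linear") nrow(readout$W) else nrow(readout$W1)
  if (ncol(features) != din) {
    stop("readout width mismatch: expected ", din, " features, got ",
         ncol(features))
  }
  if (readout$mode == "linear") {
    sweep(features %*% readout$W, 2L, readout$b, "+")
  } else {
    h <- relu(sweep(features %*% readout$W1, 2L, readout$b1, "+"))
    sweep(h %*% readout$W2, 2L, readout$b2, "+")
  }
}
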