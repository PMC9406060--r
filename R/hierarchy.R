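#' Select effectively encoded source voxels
#'
#' Voxels whose validation accuracy strictly exceeds the validity threshold
#' (rho > threshold; the published cutoff is 0.27 at p < 0.001 from the
#' shuffle null). Order-preserving. Undefined-accuracy voxels are never
#' selected.
#'
#' @param accuracy an `accuracy_vector` or bare numeric rho vector.
#' @param threshold correlation cutoff (default 0.27).
#' @return integer vector of selected voxel indices.
#' @examples
#' select_effective_voxels(c(0.5, 0.1, 0.28), threshold = 0.27)  # 1, 3
#' @export
select_effective_voxels <- function(accuracy, threshold = 0.27) {
  accuracy <- as_accuracy_vector(accuracy, threshold = threshold)
  idx <- which(accuracy$defined & accuracy$rho > threshold)
  if (length(idx) == 0L) {
    stop("no voxel exceeds the validity threshold (rho > ", threshold,
         "); a hierarchical readout would have zero inputs")
  }
  idx
}

#' Extract the stage-1 representation space
#'
#' Freezes a trained stage-1 encoder and extracts either its flattened last
#' convolutional layer (`mode = "feature"`, the feature perspective) or its
#' predicted voxel space restricted to the selected effective source voxels
#' (`mode = "voxel"`, the voxel perspective). The encoder weights are not
#' modified.
#'
#' @param model a fitted `s2v_model` (see [train_stage1()]) or a
#'   `gabornet_weights` list.
#' @param stimuli stimulus matrix/array.
#' @param mode `"voxel"` or `"feature"`.
#' @param selected integer indices of effective source voxels (required in
#'   voxel mode; see [select_effective_voxels()]).
#' @return a `representation_space`: the `N x D` matrix with attributes
#'   `mode`, `source_roi`, `selected` and `checkpoint`.
#' @export
extract_representation <- function(model, stimuli,
                                   mode = c("voxel", "feature"),
                                   selected = NULL) {
  mode <- match.arg(mode)
  weights <- if (inherits(model, "s2v_model")) model$weights else model
  spec <- attr(weights, "spec")
  fw <- gabornet_forward(weights, stimuli, spec)
  if (mode == "voxel") {
    if (is.null(selected)) {
      stop("voxel-mode extraction requires `selected` effective voxel indices")
    }
    if (is.null(fw$pred)) stop("stage-1 model has no voxel readout")
    rep <- fw$pred[, selected, drop = FALSE]
  } else {
    rep <- fw$features
  }
  structure(rep, class = c("representation_space", class(rep)),
            mode = mode,
            source_roi = if (inherits(model, "s2v_model")) model$roi else NA,
            selected = selected,
            checkpoint = if (inherits(model, "s2v_model"))
              model$checkpoint_id else NA)
}

#' @export
print.representation_space <- function(x, ...) {
  cat(sprintf("Representation space (%s mode): %d samples x %d dims",
              attr(x, "mode"), nrow(x), ncol(x)))
  if (!is.na(attr(x, "source_roi"))) cat(", source", attr(x, "source_roi"))
  cat("\n")
  invisible(x)
}

#' Initialise the two-layer hierarchical readout
#'
#' The voxel-to-voxel (V2VM) / feature-to-voxel (F2VM) readout: two affine
#' maps with a rectifier between them. The latent width equals the target
#' ROI's voxel count unless overridden.
#'
#' @param d_in source representation width.
#' @param n_voxels target ROI voxel count.
#' @param latent latent width (default `n_voxels`).
#' @param seed optional RNG seed.
#' @return readout weight list (`mode = "nonlinear"`, `W1`, `b1`, `W2`, `b2`).
#' @export
hier_readout_init <- function(d_in, n_voxels, latent = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init_readout(readout_spec(d_in, n_voxels, mode = "nonlinear",
                            latent = latent))
}

#' Hierarchical readout forward pass
#'
#' @param rep `N x D` representation matrix.
#' @param weights readout weights from [hier_readout_init()].
#' @return `N x V_target` predicted voxel matrix.
#' @export
hier_readout_forward <- function(rep, weights) {
  readout_forward(unclass(rep), weights)
}

#' Weight-squaring backpropagation rule
#'
#' Gates the raw gradient of the FIRST affine map of the hierarchical readout
#' elementwise by the squared weight matrix: `g <- g * W^2`, applied before
#' the optimizer step. Connections with large |w| ("intimate" source voxels)
#' receive amplified updates, small-|w| ("distant") connections are
#' suppressed, and the gradient sign is preserved; the forward map is
#' unchanged.
#'
#' @param raw_gradient gradient array, same shape as `W1`.
#' @param W1 first-layer weight matrix.
#' @return the gated gradient.
#' @examples
#' apply_squared_weight_rule(0.1, 2)  # 0.4
#' @export
apply_squared_weight_rule <- function(raw_gradient, W1) {
  if (!all(dim(as.matrix(raw_gradient)) == dim(as.matrix(W1)))) {
    stop("gradient and weight shapes differ")
  }
  raw_gradient * (W1 * W1)
}
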