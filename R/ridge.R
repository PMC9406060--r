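#' Closed-form ridge regression with intercept
#'
#' Centers features and responses on the training split and solves
#' `(X'X + lambda I) W = X'Y` (primal) or the equivalent dual system when
#' the feature dimension exceeds the sample count.
#'
#' @param X `N x D` training features, `Y` `N x V` responses.
#' @param lambda non-negative penalty.
#' @return list with `W` (`D x V`), intercept `b` (`V`), and the column means
#'   used for centering.
#' @keywords internal
ridge_fit <- function(X, Y, lambda) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  n <- nrow(Xc); d <- ncol(Xc)
  W <- tryCatch({
    if (d <= n) {
      A <- crossprod(Xc)
      diag(A) <- diag(A) + lambda
      solve(A, crossprod(Xc, Yc))
    } else {
      A <- tcrossprod(Xc)
      diag(A) <- diag(A) + lambda
      crossprod(Xc, solve(A, Yc))
    }
  }, error = function(e) {
    if (lambda == 0) {
      stop("ridge system is rank deficient at lambda = 0; use lambda > 0")
    }
    stop(e)
  })
  list(W = W, b = as.numeric(my - crossprod(W, mx)), mx = mx)
}

ridge_predict <- function(fit, X) {
  sweep(as.matrix(X) %*% fit$W, 2L, fit$b, "+")
}

#' Ridge encoding model over multi-layer image features
#'
#' The control encoding model: for every layer of a pluggable feature
#' extractor and every penalty on a grid, fits a closed-form ridge map from
#' the layer's features to the ROI's voxels, selects the (layer, lambda)
#' combination with the best mean training-set accuracy, and reports
#' validation predictions of the selected model. With `per_voxel = TRUE`
#' the selection is made independently per voxel instead of per ROI.
#'
#' @param features named list (in layer order) of `N x D_l` training feature
#'   matrices; the published control uses 7 layers (five pooling + two fully
#'   connected) of a pretrained object-recognition network.
#' @param features_val matching list of validation feature matrices.
#' @param responses,responses_val `N x V` voxel response matrices.
#' @param lambdas positive penalty grid (default `10^seq(-2, 4, length 7)`).
#' @param threshold validity threshold carried into the accuracy vector.
#' @param per_voxel select the best layer per voxel rather than per ROI.
#' @return object of class `ridge_encoder`: `selected` layer (and lambda),
#'   per-layer training scores, `val_accuracy`, `val_pred`, and the fitted
#'   map(s).
#' @export
ridge_encode <- function(features, features_val, responses, responses_val,
                         lambdas = 10^seq(-2, 4, length.out = 7),
                         threshold = 0.27, per_voxel = FALSE) {
  stopifnot(is.list(features), length(features) >= 1L,
            length(features) == length(features_val))
  if (is.null(names(features)) || anyDuplicated(names(features))) {
    stop("`features` must be a uniquely named list of layers")
  }
  if (length(lambdas) == 0L || any(lambdas < 0)) {
    stop("`lambdas` must be a nonempty grid of non-negative penalties")
  }
  Y <- as.matrix(responses); Yv <- as.matrix(responses_val)
  ns <- vapply(features, nrow, integer(1))
  if (length(unique(ns)) != 1L || ns[1L] != nrow(Y)) {
    stop("all feature layers must share the response sample count")
  }

  grid <- expand.grid(layer = names(features), lambda = lambdas,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  scores <- numeric(nrow(grid))
  rho_train <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- ridge_fit(features[[grid$layer[i]]], Y, grid$lambda[i])
    fits[[i]] <- f
    acc <- pearson_accuracy(Y, ridge_predict(f, features[[grid$layer[i]]]),
                            threshold = threshold)
    rho_train[[i]] <- acc$rho
    scores[i] <- if (any(acc$defined)) mean(acc$rho[acc$defined]) else -Inf
  }

  if (!per_voxel) {
    best <- which.max(scores)
    pred_val <- ridge_predict(fits[[best]],
                              features_val[[grid$layer[best]]])
    selected <- grid[best, , drop = FALSE]
  } else {
    R <- do.call(cbind, lapply(rho_train, function(r) {
      r[is.na(r)] <- -Inf
      r
    }))
    best_per_voxel <- apply(R, 1L, which.max)
    pred_val <- matrix(NA_real_, nrow(Yv), ncol(Yv))
    for (i in unique(best_per_voxel)) {
      vox <- which(best_per_voxel == i)
      f <- fits[[i]]
      fsub <- list(W = f$W[, vox, drop = FALSE], b = f$b[vox])
      pred_val[, vox] <- ridge_predict(fsub,
                                       features_val[[grid$layer[i]]])
    }
    selected <- grid[unique(best_per_voxel), , drop = FALSE]
    best <- best_per_voxel
  }

  structure(list(selected = selected, best = best, grid = grid,
                 train_scores = scores,
                 fit = if (!per_voxel) fits[[which.max(scores)]] else fits,
                 per_voxel = per_voxel,
                 val_pred = pred_val,
                 val_accuracy = pearson_accuracy(Yv, pred_val,
                                                 threshold = threshold)),
            class = "ridge_encoder")
}

#' @export
print.ridge_encoder <- function(x, ...) {
  cat("Ridge encoding model")
  if (!x$per_voxel) {
    cat(sprintf(": selected layer %s (lambda = %.3g)\n",
                x$selected$layer[1L], x$selected$lambda[1L]))
  } else cat(" (per-voxel layer selection)\n")
  print(x$val_accuracy)
  invisible(x)
}

#' Fixed-seed random-weight multi-layer feature extractor
#'
#' A stand-in for a pretrained object-recognition backbone: a small random
#' convolutional stack whose five spatial stages ("pool1".."pool5") and two
#' random projections ("fc6", "fc7") mimic the 7-layer shape of the
#' published control model. Weights are drawn once from the seed, so
#' extraction is deterministic. This extractor carries no learned visual
#' knowledge; a pretrained backend (requiring downloaded weights) can be
#' plugged in through the same interface.
#'
#' @param side stimulus side length.
#' @param seed RNG seed.
#' @return a function `f(stimuli)` returning the named list of 7 feature
#'   matrices.
#' @export
random_feature_extractor <- function(side, seed = 1L) {
  set.seed(seed)
  ch <- c(1L, 8L, 16L, 16L, 16L, 16L)
  ks <- c(5L, 3L, 3L, 3L, 3L)
  ps <- c(2L, 1L, 1L, 1L, 1L)
  dims <- integer(6L); dims[1L] <- side
  Wc <- vector("list", 5L)
  for (l in 1:5) {
    dims[l + 1L] <- conv_out_dim(dims[l], ks[l], 2L, ps[l])
    fan <- ch[l] * ks[l]^2
    Wc[[l]] <- matrix(rnorm(ch[l + 1L] * fan, sd = sqrt(2 / fan)),
                      ch[l + 1L], fan)
  }
  d5 <- ch[6L] * dims[6L]^2
  W6 <- matrix(rnorm(d5 * 128L, sd = sqrt(2 / d5)), d5, 128L)
  W7 <- matrix(rnorm(128L * 64L, sd = sqrt(2 / 128)), 128L, 64L)

  function(stimuli) {
    X <- stimuli
    if (is.array(X) && length(dim(X)) == 3L) {
      X <- matrix(X, dim(X)[1L], dim(X)[2L] * dim(X)[3L])
    }
    if (ncol(X) != side^2) {
      stop("extractor built for side ", side, ", got ", ncol(X), " pixels")
    }
    out <- vector("list", 7L)
    names(out) <- c(paste0("pool", 1:5), "fc6", "fc7")
    a <- X - rowMeans(X)
    for (l in 1:5) {
      a <- relu(conv2d_forward_cpp(a, Wc[[l]], rep(0, nrow(Wc[[l]])),
                                   ch[l], dims[l], dims[l], ks[l], 2L, ps[l]))
      out[[l]] <- a
    }
    out$fc6 <- relu(a %*% W6)
    out$fc7 <- relu(out$fc6 %*% W7)
    out
  }
}
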