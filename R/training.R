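#' Training configuration
#'
#' Defaults follow the published schedule: 90 epochs in total, the first 50
#' (the low-level visual encoding stage) training the Gabor encoder on the
#' source area, the remaining 40 (the hierarchical information conveyance
#' stage) training the two-layer readout on the target area; Adam at learning
#' rate 0.001 with batch size 64 and mean-squared-error loss.
#'
#' @param epochs total epochs (default 90).
#' @param boundary stage boundary (default 50); stage 1 runs epochs
#'   `1..boundary`, stage 2 the remaining `epochs - boundary`.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr learning rate (default 0.001).
#' @param batch_size minibatch size (default 64).
#' @param loss `"mse"`.
#' @param seed RNG seed controlling batching and initialisation.
#' @param squared_weight_rule gate the first-layer readout gradient by the
#'   squared weights during stage 2 (default `TRUE`).
#' @param validity_threshold correlation cutoff for effective-voxel selection
#'   (default 0.27).
#' @param stage1_readout readout mode of the stage-1 encoder (`"linear"` is
#'   the classic encoder; `"nonlinear"` is the fine-tuned variant whose
#'   readout matches the hierarchical one).
#' @export
train_config <- function(epochs = 90L, boundary = 50L, optimizer = c("adam", "sgd"),
                         lr = 0.001, batch_size = 64L, loss = "mse", seed = 1L,
                         squared_weight_rule = TRUE, validity_threshold = 0.27,
                         stage1_readout = c("linear", "nonlinear")) {
  optimizer <- match.arg(optimizer)
  stage1_readout <- match.arg(stage1_readout)
  stopifnot(boundary > 0, boundary < epochs, lr >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), boundary = as.integer(boundary),
                 optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed),
                 squared_weight_rule = squared_weight_rule,
                 validity_threshold = validity_threshold,
                 stage1_readout = stage1_readout),
            class = "train_config")
}

# ---- optimizer -------------------------------------------------------------

optim_init <- function(params) {
  list(t = 0L, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

optim_step <- function(params, grads, state, config,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (config$optimizer == "sgd") {
    for (k in names(grads)) params[[k]] <- params[[k]] - config$lr * grads[[k]]
    return(list(params = params, state = state))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      config$lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- stage-1 parameter plumbing -------------------------------------------

GABOR_PAR <- c("theta", "lambda", "sigma", "gamma", "psi")

flatten_stage1 <- function(w) {
  out <- c(unclass(w$gabor)[GABOR_PAR],
           list(b1 = w$b1, W2 = w$W2, b2 = w$b2, W3 = w$W3, b3 = w$b3))
  if (!is.null(w$readout)) {
    ro <- w$readout
    out <- c(out, if (ro$mode == "linear") list(roW = ro$W, rob = ro$b)
             else list(roW1 = ro$W1, rob1 = ro$b1, roW2 = ro$W2, rob2 = ro$b2))
  }
  out
}

unflatten_stage1 <- function(flat, template) {
  w <- template
  for (k in GABOR_PAR) w$gabor[[k]] <- flat[[k]]
  w$b1 <- flat$b1; w$W2 <- flat$W2; w$b2 <- flat$b2
  w$W3 <- flat$W3; w$b3 <- flat$b3
  if (!is.null(w$readout)) {
    if (w$readout$mode == "linear") {
      w$readout$W <- flat$roW; w$readout$b <- flat$rob
    } else {
      w$readout$W1 <- flat$roW1; w$readout$b1 <- flat$rob1
      w$readout$W2 <- flat$roW2; w$readout$b2 <- flat$rob2
    }
  }
  w
}

# Keep the trainable Gabor parameters inside their valid domain after each
# optimizer step (lambda, sigma, gamma must stay > 0).
clamp_gabor <- function(flat) {
  flat$lambda <- pmax(flat$lambda, 1)
  flat$sigma <- pmax(flat$sigma, 0.5)
  flat$gamma <- pmax(flat$gamma, 0.05)
  flat
}

# Full backward pass for one minibatch; X is the prepared stimulus batch.
stage1_grads <- function(w, spec, fw, y) {
  k <- spec$kernel_sizes; s <- spec$strides; p <- spec$paddings
  d <- spec$dims; inch <- spec$in_channels
  B <- nrow(y); V <- ncol(y)
  grads <- list()

  dPred <- 2 * (fw$pred - y) / (B * V)
  ro <- w$readout
  if (ro$mode == "linear") {
    grads$roW <- crossprod(fw$conv3, dPred)
    grads$rob <- colSums(dPred)
    dA3 <- tcrossprod(dPred, ro$W)
  } else {
    zh <- sweep(fw$conv3 %*% ro$W1, 2L, ro$b1, "+")
    h <- relu(zh)
    grads$roW2 <- crossprod(h, dPred)
    grads$rob2 <- colSums(dPred)
    dZh <- tcrossprod(dPred, ro$W2) * (zh > 0)
    grads$roW1 <- crossprod(fw$conv3, dZh)
    grads$rob1 <- colSums(dZh)
    dA3 <- tcrossprod(dZh, ro$W1)
  }

  dZ3 <- dA3 * (fw$pre$z3 > 0)
  bk3 <- conv2d_backward_cpp(fw$conv2, w$W3, dZ3, inch[3L], d[[2L]][2L],
                             d[[2L]][3L], k[3L], s[3L], p[3L], TRUE)
  grads$W3 <- bk3$dW; grads$b3 <- as.numeric(bk3$db)

  dZ2 <- bk3$dX * (fw$pre$z2 > 0)
  bk2 <- conv2d_backward_cpp(fw$conv1, w$W2, dZ2, inch[2L], d[[1L]][2L],
                             d[[1L]][3L], k[2L], s[2L], p[2L], TRUE)
  grads$W2 <- bk2$dW; grads$b2 <- as.numeric(bk2$db)

  dZ1 <- bk2$dX * (fw$pre$z1 > 0)
  Wg <- gabor_bank(w$gabor, k[1L], grads = TRUE)
  bk1 <- conv2d_backward_cpp(fw$pre$X, Wg$weights, dZ1, 1L, spec$image_size,
                             spec$image_size, k[1L], s[1L], p[1L], FALSE)
  grads$b1 <- as.numeric(bk1$db)
  n_tuple <- length(w$gabor$theta)
  for (par in GABOR_PAR) {
    rs <- rowSums(bk1$dW * Wg$grads[[par]])
    grads[[par]] <- rs[seq_len(n_tuple)] + rs[n_tuple + seq_len(n_tuple)]
  }
  grads
}

resolve_data <- function(data, roi) {
  if (inherits(data, "hvem_dataset")) {
    if (!roi %in% names(data$responses)) {
      stop("ROI ", roi, " not present in dataset (has: ",
           paste(names(data$responses), collapse = ", "), ")")
    }
    list(x_train = data$stimuli$train, x_val = data$stimuli$val,
         y_train = data$responses[[roi]]$train,
         y_val = data$responses[[roi]]$val)
  } else {
    stop("`data` must be an hvem_dataset (see generate_dataset()/read_vim1())")
  }
}

#' Train the stage-1 Gabor encoder on a source visual area
#'
#' Runs the low-level visual encoding stage: minibatch Adam on the
#' mean-squared error between predicted and measured source-area voxel
#' activity, for `epochs` epochs (default: the configured stage boundary,
#' 50). After every epoch the mean validation accuracy (Pearson rho over the
#' ROI's defined voxels) is recorded, and the returned model carries the
#' weights from the best-validation epoch (ties resolved to the earliest).
#'
#' @param data an `hvem_dataset` (from [generate_dataset()] or
#'   [read_vim1()]).
#' @param roi source ROI label (e.g. `"V1"`, `"V2"`).
#' @param config a [train_config()].
#' @param spec a [backbone_spec()]; defaults to one matching the dataset's
#'   stimulus side.
#' @param epochs number of stage-1 epochs (default `config$boundary`);
#'   `epochs = 0` returns the initialised weights unchanged.
#' @param readout readout mode; defaults to `config$stage1_readout`.
#' @param init optional `gabornet_weights` to start from.
#' @param verbose print per-epoch progress.
#' @return an object of class `s2v_model`: best-epoch `weights`, the full
#'   per-epoch `trace` (train loss, mean validation rho), `best_epoch`,
#'   `val_accuracy` (an `accuracy_vector` at the selected checkpoint), `roi`,
#'   `spec`, `config`.
#' @export
train_stage1 <- function(data, roi, config = train_config(), spec = NULL,
                         epochs = config$boundary, readout = NULL,
                         init = NULL, verbose = FALSE) {
  dd <- resolve_data(data, roi)
  if (nrow(dd$x_train) != nrow(dd$y_train)) {
    stop("stimulus/response sample mismatch: ", nrow(dd$x_train), " vs ",
         nrow(dd$y_train))
  }
  if (is.null(spec)) {
    spec <- backbone_spec(image_size = as.integer(sqrt(ncol(dd$x_train))))
  }
  if (is.null(readout)) readout <- config$stage1_readout
  set.seed(config$seed)
  w <- if (is.null(init)) {
    gabornet_init(spec, n_voxels = ncol(dd$y_train), readout = readout)
  } else init

  flat <- flatten_stage1(w)
  state <- optim_init(flat)
  n <- nrow(dd$x_train)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_mean_rho = numeric(0))
  best <- list(score = -Inf, epoch = 0L, flat = flat)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batch <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      w <- unflatten_stage1(flat, w)
      fw <- gabornet_forward(w, dd$x_train[idx, , drop = FALSE], spec,
                             keep_pre = TRUE)
      y <- dd$y_train[idx, , drop = FALSE]
      loss <- mean((fw$pred - y)^2)
      n_batch <- n_batch + 1L
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep, ", batch ", n_batch)
      }
      ep_loss <- ep_loss + loss
      grads <- stage1_grads(w, spec, fw, y)
      upd <- optim_step(flat, grads, state, config)
      flat <- clamp_gabor(upd$params); state <- upd$state
    }
    w <- unflatten_stage1(flat, w)
    acc <- pearson_accuracy(dd$y_val,
                            gabornet_forward(w, dd$x_val, spec)$pred,
                            threshold = config$validity_threshold)
    score <- if (any(acc$defined)) mean(acc$rho[acc$defined]) else -Inf
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / n_batch,
                                     val_mean_rho = score))
    if (score > best$score) best <- list(score = score, epoch = ep, flat = flat)
    if (verbose) {
      message(sprintf("stage1 epoch %d/%d loss %.4f val rho %.3f", ep, epochs,
                      ep_loss / n_batch, score))
    }
  }

  w_best <- unflatten_stage1(best$flat, w)
  acc <- pearson_accuracy(dd$y_val,
                          gabornet_forward(w_best, dd$x_val, spec)$pred,
                          threshold = config$validity_threshold)
  structure(list(weights = w_best, spec = spec, roi = roi, config = config,
                 trace = trace, best_epoch = best$epoch, val_accuracy = acc,
                 checkpoint_id = sprintf("s2v-%s-seed%d-ep%d", roi,
                                         config$seed, best$epoch)),
            class = "s2v_model")
}

#' @export
predict.s2v_model <- function(object, newdata, ...) {
  gabornet_forward(object$weights, newdata, object$spec)$pred
}

#' @export
print.s2v_model <- function(x, ...) {
  cat("Stage-1 Gabor encoder (", x$weights$readout$mode, " readout), ROI ",
      x$roi, "\n", sep = "")
  cat("  trained ", nrow(x$trace), " epochs; best epoch ", x$best_epoch,
      " (mean val rho ",
      sprintf("%.3f", if (x$best_epoch > 0)
        x$trace$val_mean_rho[x$best_epoch] else NA), ")\n", sep = "")
  print(x$val_accuracy)
  invisible(x)
}

#' @export
summary.s2v_model <- function(object, k = 50L, ...) {
  acc <- object$val_accuracy
  out <- list(roi = object$roi, epochs = nrow(object$trace),
              best_epoch = object$best_epoch,
              n_voxels = length(acc$rho), n_valid = sum(acc$valid),
              mean_rho = mean(acc$rho[acc$defined]),
              topk = tryCatch(topk_average_accuracy(acc, k), error = function(e) NA),
              k = k)
  class(out) <- "summary.s2v_model"
  out
}

#' @export
print.summary.s2v_model <- function(x, ...) {
  cat(sprintf("ROI %s: %d voxels, %d valid; mean rho %.3f; Top-%d AA %.3f (best epoch %d)\n",
              x$roi, x$n_voxels, x$n_valid, x$mean_rho, x$k, x$topk,
              x$best_epoch))
  invisible(x)
}

#' @export
plot.s2v_model <- function(x, ...) {
  plot(x$trace$epoch, x$trace$val_mean_rho, type = "b",
       xlab = "epoch", ylab = "mean validation rho",
       main = paste("Stage-1 training,", x$roi), ...)
  abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' @export
coef.s2v_model <- function(object, ...) {
  object$weights$readout
}

#' Train the stage-2 hierarchical readout on a target visual area
#'
#' Runs the hierarchical information conveyance stage: the frozen stage-1
#' representation is mapped to target-area voxels through the two-layer
#' readout, trained with minibatch Adam on mean-squared error. When the
#' weight-squaring rule is active (the default), the raw gradient of the
#' first affine map is gated elementwise by the squared weights before the
#' optimizer step (see [apply_squared_weight_rule()]). Feature-mode
#' representations are standardised per dimension using training-split
#' statistics. The best-validation checkpoint is returned.
#'
#' @param rep,rep_val training/validation `representation_space` (or plain
#'   matrices).
#' @param responses,responses_val matching `N x V_target` response matrices.
#' @param config a [train_config()].
#' @param epochs number of stage-2 epochs (default
#'   `config$epochs - config$boundary`, i.e. 40).
#' @param latent latent width (default: target voxel count).
#' @param standardize standardise representation dimensions (default: `TRUE`
#'   for feature-mode input, `FALSE` for voxel-mode).
#' @return object of class `hier_model` with the readout `weights`, `trace`,
#'   `best_epoch`, `val_accuracy`, and standardisation parameters.
#' @export
train_stage2 <- function(rep, responses, rep_val, responses_val,
                         config = train_config(),
                         epochs = config$epochs - config$boundary,
                         latent = NULL, standardize = NULL) {
  mode <- attr(rep, "mode")
  if (is.null(standardize)) standardize <- identical(mode, "feature")
  X <- unclass(as.matrix(rep)); Xv <- unclass(as.matrix(rep_val))
  y <- as.matrix(responses); yv <- as.matrix(responses_val)
  if (nrow(X) != nrow(y)) stop("representation/response sample mismatch")
  if (ncol(X) != ncol(Xv)) stop("train/val representation widths differ")
  mu <- NULL; sdv <- NULL
  if (standardize) {
    # Regularized per-dimension standardization: dividing by sd_d alone
    # explodes near-dead rectified feature dimensions (sd ~ 0) into pure
    # noise axes; adding the mean sd bounds the feature scale while
    # preserving the relative salience of live dimensions.
    mu <- colMeans(X)
    raw_sd <- apply(X, 2L, sd)
    sdv <- pmax(raw_sd + mean(raw_sd), 1e-8)
    X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    Xv <- sweep(sweep(Xv, 2L, mu), 2L, sdv, "/")
  }

  set.seed(config$seed + 1L)
  ro <- hier_readout_init(ncol(X), ncol(y), latent = latent)
  params <- list(W1 = ro$W1, b1 = ro$b1, W2 = ro$W2, b2 = ro$b2)
  state <- optim_init(params)
  n <- nrow(X)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_mean_rho = numeric(0))
  best <- list(score = -Inf, epoch = 0L, params = params)

  fwd <- function(P, M) {
    zh <- sweep(M %*% P$W1, 2L, P$b1, "+")
    h <- relu(zh)
    list(zh = zh, h = h, pred = sweep(h %*% P$W2, 2L, P$b2, "+"))
  }

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batch <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
      f <- fwd(params, Xb)
      loss <- mean((f$pred - yb)^2)
      n_batch <- n_batch + 1L
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep, ", batch ", n_batch)
      }
      ep_loss <- ep_loss + loss
      dPred <- 2 * (f$pred - yb) / (nrow(yb) * ncol(yb))
      gW2 <- crossprod(f$h, dPred); gb2 <- colSums(dPred)
      dZh <- tcrossprod(dPred, params$W2) * (f$zh > 0)
      gW1 <- crossprod(Xb, dZh); gb1 <- colSums(dZh)
      if (config$squared_weight_rule) {
        gW1 <- apply_squared_weight_rule(gW1, params$W1)
      }
      upd <- optim_step(params, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                        state, config)
      params <- upd$params; state <- upd$state
    }
    acc <- pearson_accuracy(yv, fwd(params, Xv)$pred,
                            threshold = config$validity_threshold)
    score <- if (any(acc$defined)) mean(acc$rho[acc$defined]) else -Inf
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / n_batch,
                                     val_mean_rho = score))
    if (score > best$score) best <- list(score = score, epoch = ep,
                                         params = params)
  }

  P <- best$params
  weights <- list(mode = "nonlinear", W1 = P$W1, b1 = P$b1, W2 = P$W2,
                  b2 = P$b2)
  acc <- pearson_accuracy(yv, fwd(P, Xv)$pred,
                          threshold = config$validity_threshold)
  structure(list(weights = weights, rep_mode = mode, mu = mu, sd = sdv,
                 config = config, trace = trace, best_epoch = best$epoch,
                 val_accuracy = acc),
            class = "hier_model")
}

#' @export
predict.hier_model <- function(object, newdata, ...) {
  X <- unclass(as.matrix(newdata))
  if (!is.null(object$mu)) {
    X <- sweep(sweep(X, 2L, object$mu), 2L, object$sd, "/")
  }
  hier_readout_forward(X, object$weights)
}

#' @export
print.hier_model <- function(x, ...) {
  cat("Hierarchical readout (", if (identical(x$rep_mode, "voxel")) "V2VM"
      else "F2VM", "): ", nrow(x$weights$W1), " -> ", ncol(x$weights$W1),
      " -> ", ncol(x$weights$W2), "\n", sep = "")
  cat("  best epoch ", x$best_epoch, " of ", nrow(x$trace), "\n", sep = "")
  print(x$val_accuracy)
  invisible(x)
}

ROI_ORDER <- c(V1 = 1L, V2 = 2L, V4 = 3L, LO = 4L)

#' Hierarchical pipeline specification
#'
#' Names the source and target visual areas and the conveyance perspective.
#' The ventral-stream ordering V1 < V2 < V4 < LO is enforced: the source must
#' strictly precede the target (for equal areas, use the plain encoder
#' instead).
#'
#' @param source,target ROI labels among V1, V2, V4, LO.
#' @param mode `"s2v2v"` (voxel perspective) or `"s2f2v"` (feature
#'   perspective).
#' @export
pipeline_spec <- function(source, target, mode = c("s2v2v", "s2f2v")) {
  mode <- match.arg(mode)
  if (!source %in% names(ROI_ORDER) || !target %in% names(ROI_ORDER)) {
    stop("ROIs must be among ", paste(names(ROI_ORDER), collapse = ", "))
  }
  if (source == target) {
    stop("source and target areas are identical; use the plain encoder instead")
  }
  if (ROI_ORDER[[source]] > ROI_ORDER[[target]]) {
    stop("ventral-stream order violated: ", source, " does not precede ",
         target)
  }
  structure(list(source = source, target = target, mode = mode),
            class = "pipeline_spec")
}

#' Run a full hierarchical encoding pipeline
#'
#' Composes the two training stages: fits (or reuses) the stage-1 encoder on
#' the source area, selects the effectively encoded source voxels (voxel
#' mode), extracts the frozen representation, trains the hierarchical readout
#' on the target area, and evaluates per-voxel validation accuracy there.
#'
#' @param spec a [pipeline_spec()].
#' @param data an `hvem_dataset`.
#' @param config a [train_config()].
#' @param stage1 optionally a pre-trained `s2v_model` for the source area
#'   (reused across targets); trained from scratch when `NULL`.
#' @param stage1_epochs,stage2_epochs epoch overrides for reduced-scale runs.
#' @return object of class `hier_pipeline` with elements `spec`, `stage1`,
#'   `selected` (voxel mode), `stage2`, and `val_accuracy` on the target
#'   validation split.
#' @export
run_pipeline <- function(spec, data, config = train_config(), stage1 = NULL,
                         stage1_epochs = config$boundary,
                         stage2_epochs = config$epochs - config$boundary) {
  stopifnot(inherits(spec, "pipeline_spec"))
  if (is.null(stage1)) {
    stage1 <- train_stage1(data, spec$source, config, epochs = stage1_epochs)
  } else if (!identical(stage1$roi, spec$source)) {
    stop("supplied stage-1 model was trained on ", stage1$roi,
         ", but the pipeline source is ", spec$source)
  }
  stage1_snapshot <- flatten_stage1(stage1$weights)

  selected <- NULL
  if (spec$mode == "s2v2v") {
    selected <- select_effective_voxels(stage1$val_accuracy,
                                        config$validity_threshold)
    rep_tr <- extract_representation(stage1, data$stimuli$train, "voxel",
                                     selected)
    rep_val <- extract_representation(stage1, data$stimuli$val, "voxel",
                                      selected)
  } else {
    rep_tr <- extract_representation(stage1, data$stimuli$train, "feature")
    rep_val <- extract_representation(stage1, data$stimuli$val, "feature")
  }
  yt <- data$responses[[spec$target]]
  if (is.null(yt)) stop("target ROI ", spec$target, " missing from dataset")
  stage2 <- train_stage2(rep_tr, yt$train, rep_val, yt$val, config,
                         epochs = stage2_epochs)
  stopifnot(identical(stage1_snapshot, flatten_stage1(stage1$weights)))

  structure(list(spec = spec, stage1 = stage1, selected = selected,
                 stage2 = stage2, config = config,
                 val_accuracy = stage2$val_accuracy),
            class = "hier_pipeline")
}

#' @export
predict.hier_pipeline <- function(object, newdata, ...) {
  rep <- if (object$spec$mode == "s2v2v") {
    extract_representation(object$stage1, newdata, "voxel", object$selected)
  } else {
    extract_representation(object$stage1, newdata, "feature")
  }
  predict(object$stage2, rep)
}

#' @export
print.hier_pipeline <- function(x, ...) {
  cat(sprintf("Hierarchical encoding pipeline %s -> %s (%s)\n",
              x$spec$source, x$spec$target, toupper(x$spec$mode)))
  if (!is.null(x$selected)) {
    cat("  effective source voxels:", length(x$selected), "\n")
  }
  print(x$val_accuracy)
  invisible(x)
}

#' @export
summary.hier_pipeline <- function(object, k = 50L, ...) {
  acc <- object$val_accuracy
  cat(sprintf("%s -> %s (%s): Top-%d AA %.3f, %d/%d valid voxels\n",
              object$spec$source, object$spec$target,
              toupper(object$spec$mode), k,
              topk_average_accuracy(acc, k), sum(acc$valid),
              length(acc$rho)))
  invisible(object)
}

#' @export
plot.hier_pipeline <- function(x, ...) {
  plot(x$stage2$trace$epoch, x$stage2$trace$val_mean_rho, type = "b",
       xlab = "stage-2 epoch", ylab = "mean validation rho",
       main = sprintf("%s -> %s (%s)", x$spec$source, x$spec$target,
                      toupper(x$spec$mode)), ...)
  invisible(x)
}
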