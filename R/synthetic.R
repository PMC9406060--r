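#' Synthetic hierarchy configuration
#'
#' Describes a vim-1-shaped synthetic world with a known representational
#' hierarchy: V1 voxels are rectified quadrature Gabor energies of the
#' stimulus; V2 voxels sparsely pool squared V1 outputs; V4 voxels are sparse
#' random mixtures of V2 passed through a smooth saturating nonlinearity
#' (tanh); LO repeats that construction over V4. Per-ROI additive Gaussian
#' noise is controlled by SNR = signal variance / noise variance, so the
#' noise ceiling of an ideal predictor is `sqrt(SNR / (1 + SNR))`.
#'
#' Named configurations: `"H1"` is the full hierarchy with SNR
#' V1:4, V2:3, V4:1, LO:0.5; `"H0"` is a noiseless V1-only world. The
#' default scale (side 64, 300 train / 60 val, ROIs V1:200 V2:150 V4:100
#' LO:60) keeps reduced-scale testing fast; pass `n_train = 1750`,
#' `n_val = 120`, `side = 128` for the full vim-1 shape.
#'
#' @param id `"H1"` or `"H0"`.
#' @param n_train,n_val sample counts.
#' @param side stimulus side length, one of 32, 64, 128.
#' @param roi_sizes named integer vector of voxel counts.
#' @param snr named numeric vector of per-ROI SNRs (`Inf` = noiseless); must
#'   be positive.
#' @param pool_size number of V1 voxels pooled per V2 voxel (and mixing
#'   sparsity of the higher stages).
#' @export
synthetic_config <- function(id = c("H1", "H0"), n_train = 300L, n_val = 60L,
                             side = 64L,
                             roi_sizes = c(V1 = 200L, V2 = 150L, V4 = 100L,
                                           LO = 60L),
                             snr = c(V1 = 4, V2 = 3, V4 = 1, LO = 0.5),
                             pool_size = 10L) {
  id <- match.arg(id)
  if (!side %in% c(32L, 64L, 128L)) {
    stop("side must be one of 32, 64, 128; got ", side)
  }
  if (id == "H0") {
    roi_sizes <- roi_sizes[intersect("V1", names(roi_sizes))]
    snr <- c(V1 = Inf)
  }
  if (any(snr <= 0)) stop("SNR must be positive (use Inf for noiseless)")
  if (!all(names(roi_sizes) %in% names(ROI_ORDER))) {
    stop("roi_sizes names must be among ", paste(names(ROI_ORDER), collapse = ", "))
  }
  structure(list(id = id, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), side = as.integer(side),
                 roi_sizes = roi_sizes, snr = snr,
                 pool_size = as.integer(pool_size)),
            class = "synthetic_config")
}

# radially symmetric 1/f amplitude spectrum noise, unit sd
one_over_f_noise <- function(side) {
  fy <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  f <- sqrt(outer(fy^2, fy^2, "+"))
  f[1L, 1L] <- 1
  spec <- fft(matrix(rnorm(side^2), side)) / f
  x <- Re(fft(spec, inverse = TRUE)) / side^2
  x / max(sd(x), 1e-12)
}

gabor_patch <- function(theta, lambda, sigma, psi, support) {
  g <- gabor_grid(support)
  xp <- g$x * cos(theta) + g$y * sin(theta)
  yp <- -g$x * sin(theta) + g$y * cos(theta)
  matrix(exp(-(xp^2 + yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + psi),
         support, support, byrow = TRUE)
}

#' Generate synthetic grayscale stimuli
#'
#' Each image is a normalised sum of 5-15 random Gabor patches (random
#' position, orientation, wavelength, phase) plus 1/f spectral noise,
#' rescaled to `[0, 1]` — a crude stand-in for grayscale natural scenes with
#' oriented local structure and a natural amplitude spectrum.
#'
#' @param n number of images.
#' @param side side length in pixels, one of 32, 64, 128.
#' @param seed RNG seed; identical `(n, side, seed)` reproduce identical
#'   arrays.
#' @return `n x side^2` matrix (row-major pixel layout, rows = images) with
#'   attribute `side`.
#' @export
generate_stimuli <- function(n, side = 64L, seed = 1L) {
  stopifnot(n >= 1)
  if (!side %in% c(32L, 64L, 128L)) {
    stop("side must be one of 32, 64, 128; got ", side)
  }
  set.seed(seed)
  X <- matrix(0, n, side * side)
  for (i in seq_len(n)) {
    img <- 0.6 * one_over_f_noise(side)
    for (j in seq_len(sample(5:15, 1L))) {
      lambda <- exp(runif(1L, log(4), log(side / 3)))
      support <- min(2L * floor(lambda) + 1L, side)
      patch <- gabor_patch(runif(1L, 0, pi), lambda, 0.5 * lambda,
                           runif(1L, 0, 2 * pi), support)
      amp <- runif(1L, 0.5, 1.5) * sample(c(-1, 1), 1L)
      cy <- sample.int(side - support + 1L, 1L)
      cx <- sample.int(side - support + 1L, 1L)
      sub <- img[cy:(cy + support - 1L), cx:(cx + support - 1L)]
      img[cy:(cy + support - 1L), cx:(cx + support - 1L)] <- sub + amp * patch
    }
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0 + 0.5
    X[i, ] <- as.vector(t(img))  # row-major: (y-1)*side + x
  }
  attr(X, "side") <- side
  X
}

# quadrature Gabor filter pair placed at (cy, cx), as flat image-weight vectors
place_filter <- function(side, cy, cx, theta, lambda, support = 9L) {
  h <- (support - 1L) %/% 2L
  gre <- gabor_patch(theta, lambda, 0.5 * lambda, 0, support)
  gim <- gabor_patch(theta, lambda, 0.5 * lambda, pi / 2, support)
  wre <- numeric(side * side); wim <- numeric(side * side)
  ys <- (cy - h):(cy + h); xs <- (cx - h):(cx + h)
  idx <- as.vector(t(outer((ys - 1L) * side, xs, "+")))
  wre[idx] <- as.vector(t(gre))
  wim[idx] <- as.vector(t(gim))
  cbind(re = wre, im = wim)
}

sparse_mix <- function(n_in, n_out, k, nonneg = FALSE) {
  M <- matrix(0, n_in, n_out)
  for (j in seq_len(n_out)) {
    rows <- sample.int(n_in, min(k, n_in))
    w <- if (nonneg) runif(length(rows), 0.3, 1) else rnorm(length(rows))
    M[rows, j] <- w
  }
  M
}

standardize_cols <- function(M) {
  M <- scale(M)
  M[, attr(M, "scaled:scale") == 0] <- 0
  matrix(as.numeric(M), nrow(M), ncol(M))
}

#' Generate a synthetic hierarchical dataset
#'
#' Draws stimuli, propagates them through the ground-truth hierarchy
#' (deterministically, stage by stage), standardises each voxel's signal to
#' unit variance, and adds independent zero-mean Gaussian noise with variance
#' `1/SNR`, so the best attainable validation accuracy per voxel is
#' `sqrt(SNR / (1 + SNR))` in expectation. Regeneration from the same
#' `(config, seed)` is bitwise identical.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return object of classes `synthetic_dataset`/`hvem_dataset`: `stimuli`
#'   (`$train`, `$val` matrices), `responses` (per ROI, `$train`/`$val`),
#'   `truth` (noiseless standardised signals per ROI), `hierarchy` (the
#'   generative weights), `config`, `seed`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_train + config$n_val
  X <- generate_stimuli(n, config$side, seed = seed)
  set.seed(seed + 1000003L)

  rois <- names(config$roi_sizes)
  side <- config$side
  hier <- list()
  signals <- list()

  nv1 <- config$roi_sizes[["V1"]]
  h <- 4L
  v1 <- list(cy = sample((h + 1L):(side - h), nv1, replace = TRUE),
             cx = sample((h + 1L):(side - h), nv1, replace = TRUE),
             theta = runif(nv1, 0, pi),
             lambda = exp(runif(nv1, log(3), log(10))))
  Wf <- matrix(0, side * side, 2L * nv1)
  for (v in seq_len(nv1)) {
    Wf[, c(v, nv1 + v)] <- place_filter(side, v1$cy[v], v1$cx[v],
                                        v1$theta[v], v1$lambda[v])
  }
  proj <- X %*% Wf
  energy <- sqrt(proj[, seq_len(nv1), drop = FALSE]^2 +
                 proj[, nv1 + seq_len(nv1), drop = FALSE]^2)
  hier$V1 <- v1
  signals$V1 <- standardize_cols(energy)

  if ("V2" %in% rois) {
    P <- sparse_mix(nv1, config$roi_sizes[["V2"]], config$pool_size,
                    nonneg = TRUE)
    hier$V2 <- P
    signals$V2 <- standardize_cols(sqrt(energy^2 %*% P))
  }
  if ("V4" %in% rois) {
    M <- sparse_mix(ncol(signals$V2), config$roi_sizes[["V4"]],
                    config$pool_size)
    hier$V4 <- M
    signals$V4 <- standardize_cols(tanh(signals$V2 %*% M /
                                        sqrt(config$pool_size)))
  }
  if ("LO" %in% rois) {
    M <- sparse_mix(ncol(signals$V4), config$roi_sizes[["LO"]],
                    config$pool_size)
    hier$LO <- M
    signals$LO <- standardize_cols(tanh(signals$V4 %*% M /
                                        sqrt(config$pool_size)))
  }

  tr <- seq_len(config$n_train)
  va <- config$n_train + seq_len(config$n_val)
  responses <- list()
  truth <- list()
  for (r in rois) {
    s <- signals[[r]]
    snr <- config$snr[[r]]
    resp <- if (is.finite(snr)) {
      s + matrix(rnorm(length(s), sd = sqrt(1 / snr)), nrow(s))
    } else s
    responses[[r]] <- list(train = resp[tr, , drop = FALSE],
                           val = resp[va, , drop = FALSE])
    truth[[r]] <- list(train = s[tr, , drop = FALSE],
                       val = s[va, , drop = FALSE])
  }

  structure(list(stimuli = list(train = X[tr, , drop = FALSE],
                                val = X[va, , drop = FALSE]),
                 responses = responses, truth = truth, hierarchy = hier,
                 config = config, seed = seed, subject = "synthetic"),
            class = c("synthetic_dataset", "hvem_dataset"))
}

#' @export
print.hvem_dataset <- function(x, ...) {
  cat("Visual encoding dataset (", if (inherits(x, "synthetic_dataset"))
    paste0("synthetic ", x$config$id) else "loaded", "): ",
      nrow(x$stimuli$train), " train / ", nrow(x$stimuli$val),
      " val stimuli, side ", sqrt(ncol(x$stimuli$train)), "\n", sep = "")
  for (r in names(x$responses)) {
    cat("  ", r, ": ", ncol(x$responses[[r]]$train), " voxels\n", sep = "")
  }
  invisible(x)
}
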