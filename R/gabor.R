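#' Trainable Gabor kernel parameters
#'
#' A bank of `n` parameter tuples (orientation `theta`, wavelength `lambda`,
#' envelope scale `sigma`, spatial aspect ratio `gamma`, phase `psi`), each of
#' which expands to one even/"real" kernel (cosine carrier, phase `psi`) and
#' one odd/"imaginary" kernel (phase `psi + pi/2`), so `n = 64` tuples yield
#' the 128 kernels of the Gabor convolutional layer.
#'
#' The default initialisation covers the 9x9 support with a conventional bank:
#' 8 orientations evenly spaced over `[0, pi)` crossed with 8 wavelengths
#' log-spaced over `[3, 10]` pixels, `sigma = 0.5 * lambda`, unit aspect
#' ratio and zero phase.
#'
#' @param n number of parameter tuples (default 64).
#' @param theta,lambda,sigma,gamma,psi optional numeric vectors of length `n`
#'   overriding the default initialisation. `lambda`, `sigma`, `gamma` must be
#'   strictly positive.
#' @return an object of class `gabor_params`: a list of the five length-`n`
#'   numeric vectors.
#' @export
gabor_params <- function(n = 64, theta = NULL, lambda = NULL, sigma = NULL,
                         gamma = NULL, psi = NULL) {
  stopifnot(n >= 1)
  n_theta <- max(1L, floor(sqrt(n)))
  n_lambda <- ceiling(n / n_theta)
  if (is.null(theta)) {
    theta <- rep(seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)],
                 times = n_lambda)[seq_len(n)]
  }
  if (is.null(lambda)) {
    lambda <- rep(10^seq(log10(3), log10(10), length.out = n_lambda),
                  each = n_theta)[seq_len(n)]
  }
  if (is.null(sigma)) sigma <- 0.5 * lambda
  if (is.null(gamma)) gamma <- rep(1, n)
  if (is.null(psi)) psi <- rep(0, n)
  p <- list(theta = as.numeric(theta), lambda = as.numeric(lambda),
            sigma = as.numeric(sigma), gamma = as.numeric(gamma),
            psi = as.numeric(psi))
  validate_gabor_params(p, n)
  structure(p, class = "gabor_params")
}

validate_gabor_params <- function(p, n = NULL) {
  len <- unique(vapply(p[c("theta", "lambda", "sigma", "gamma", "psi")],
                       length, integer(1)))
  if (length(len) != 1L) stop("gabor parameter vectors must share one length")
  if (!is.null(n) && len != n) stop("expected ", n, " parameter tuples, got ", len)
  if (any(!is.finite(unlist(p)))) stop("gabor parameters must be finite")
  if (any(p$lambda <= 0)) stop("gabor wavelength `lambda` must be > 0")
  if (any(p$sigma <= 0)) stop("gabor envelope scale `sigma` must be > 0")
  if (any(p$gamma <= 0)) stop("gabor aspect ratio `gamma` must be > 0")
  invisible(TRUE)
}

# Pointwise pieces shared by the kernel and its parameter gradients.
# Grid layout per kernel: entries ordered row-major (y slowest, x fastest),
# y and x on the centred integer grid -h..h, h = (size-1)/2.
gabor_grid <- function(size) {
  h <- (size - 1L) %/% 2L
  list(x = rep(seq(-h, h), times = size), y = rep(seq(-h, h), each = size))
}

# Evaluate the bank (and optionally parameter gradients) as flat matrices.
# Returns weights: 128 x size^2 (rows 1..64 real, 65..128 imaginary,
# index-aligned), grads: list theta/lambda/sigma/gamma/psi of 128 x size^2.
gabor_bank <- function(params, size = 9L, grads = FALSE) {
  validate_gabor_params(params)
  if (size %% 2L == 0L) stop("kernel size must be odd, got ", size)
  n <- length(params$theta)
  g <- gabor_grid(size)
  P <- size * size

  th <- params$theta; la <- params$lambda; si <- params$sigma
  ga <- params$gamma; ps <- params$psi
  XP <- outer(g$x, cos(th)) + outer(g$y, sin(th))        # P x n, x'
  YP <- -outer(g$x, sin(th)) + outer(g$y, cos(th))       # y'
  SI2 <- matrix(si^2, P, n, byrow = TRUE)
  GA2 <- matrix(ga^2, P, n, byrow = TRUE)
  LAM <- matrix(la, P, n, byrow = TRUE)
  E <- exp(-(XP^2 + GA2 * YP^2) / (2 * SI2))
  phase_re <- 2 * pi * XP / LAM + matrix(ps, P, n, byrow = TRUE)
  phase_im <- phase_re + pi / 2

  pack <- function(re, im) rbind(t(re), t(im))           # 2n x P
  out <- list(weights = pack(E * cos(phase_re), E * cos(phase_im)))

  if (grads) {
    SI <- matrix(si, P, n, byrow = TRUE)
    GA <- matrix(ga, P, n, byrow = TRUE)
    part <- function(phase) {
      C <- cos(phase); S <- sin(phase)
      dgx <- E * (-XP / SI2) * C + E * (-S) * (2 * pi / LAM)
      dgy <- E * (-GA2 * YP / SI2) * C
      list(theta = dgx * YP - dgy * XP,
           lambda = E * S * (2 * pi * XP / LAM^2),
           sigma = E * C * (XP^2 + GA2 * YP^2) / (SI2 * SI),
           gamma = -E * C * GA * YP^2 / SI2,
           psi = -E * S)
    }
    pre <- part(phase_re); pim <- part(phase_im)
    out$grads <- lapply(stats::setNames(nm = names(pre)),
                        function(k) pack(pre[[k]], pim[[k]]))
  }
  out
}

#' Build the Gabor kernel stack
#'
#' Evaluates every parameter tuple on the centred integer grid of an odd-sized
#' square support. With `x' = x cos(theta) + y sin(theta)` and
#' `y' = -x sin(theta) + y cos(theta)`, the kernel value is
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`;
#' the odd ("imaginary") partner uses phase `psi + pi/2`. Kernels 1..64 are
#' the even bank, 65..128 the odd bank, index-aligned with the tuples.
#'
#' @param params a [gabor_params()] object.
#' @param size odd kernel support in pixels (default 9).
#' @return numeric array of dimension `c(2n, 1, size, size)`; entry
#'   `[k, 1, iy, ix]` is the kernel value at `y = iy - (size+1)/2`,
#'   `x = ix - (size+1)/2`.
#' @examples
#' k <- build_gabor_kernels(gabor_params(4), size = 9)
#' dim(k)
#' @export
build_gabor_kernels <- function(params, size = 9L) {
  W <- gabor_bank(params, size)$weights
  n2 <- nrow(W)
  out <- array(0, dim = c(n2, 1L, size, size))
  for (k in seq_len(n2)) {
    # rows of W are (y slowest, x fastest); matrix(..., byrow = TRUE) restores
    # the [iy, ix] kernel image
    out[k, 1L, , ] <- matrix(W[k, ], size, size, byrow = TRUE)
  }
  out
}
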