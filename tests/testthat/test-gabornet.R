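test_that("backbone dimension chain holds for the reduced 32 px input", {
  spec <- backbone_spec(32L)
  expect_equal(vapply(spec$dims, paste, character(1), collapse = "x"),
               c("128x14x14", "128x7x7", "128x4x4"))
  expect_equal(spec$n_features, 128L * 16L)

  w <- gabornet_init(spec, n_voxels = 7L, seed = 1L)
  for (B in c(1L, 3L)) {
    X <- matrix(runif(B * 1024L), B)
    fw <- gabornet_forward(w, X, spec)
    expect_equal(dim(fw$conv1), c(B, 128L * 14L * 14L))
    expect_equal(dim(fw$conv2), c(B, 128L * 7L * 7L))
    expect_equal(dim(fw$conv3), c(B, 128L * 4L * 4L))
    expect_equal(dim(fw$pred), c(B, 7L))
  }
})

test_that("forward pass is deterministic and rejects wrong input sides", {
  spec <- backbone_spec(32L)
  w <- gabornet_init(spec, n_voxels = 3L, seed = 2L)
  X <- matrix(runif(2 * 1024L), 2)
  f1 <- gabornet_forward(w, X, spec)
  f2 <- gabornet_forward(w, X, spec)
  expect_identical(f1$pred, f2$pred)
  expect_identical(f1$conv3, f2$conv3)
  expect_error(gabornet_forward(w, matrix(runif(2 * 900L), 2), spec),
               "expected 32x32 \\(1024 pixels\\), got 900")
})

test_that("zero input with zero biases propagates to an all-zero conv3", {
  spec <- backbone_spec(32L)
  w <- gabornet_init(spec, seed = 3L)
  w$b1[] <- 0; w$b2[] <- 0; w$b3[] <- 0
  fw <- gabornet_forward(w, matrix(0, 2, 1024L), spec)
  expect_true(all(fw$conv3 == 0))
})

test_that("readout forward matches hand evaluation and checks widths", {
  ro <- list(mode = "linear", W = matrix(c(1, -1), 2, 1), b = 0.5)
  expect_equal(readout_forward(matrix(c(2, 1), 1), ro)[1, 1], 1.5)
  # zero features -> bias vector
  ro2 <- list(mode = "linear", W = matrix(0, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(as.numeric(readout_forward(matrix(0, 1, 3), ro2)), c(1, 2, 3, 4))
  expect_error(readout_forward(matrix(0, 1, 5), ro), "width mismatch")
  # nonlinear mode shares the hierarchical readout structure
  spec <- readout_spec(10L, 1535L, mode = "nonlinear")
  expect_equal(spec$latent, 1535L)
})

test_that("conv backward matches finite differences", {
  set.seed(21)
  C <- 2L; H <- 7L; K <- 3L; S <- 2L; P <- 1L; N <- 2L
  OH <- (H + 2L * P - K) %/% S + 1L
  X <- matrix(rnorm(N * C * H * H), N)
  W <- matrix(rnorm(4L * C * K * K), 4L)
  b <- rnorm(4L)
  R <- matrix(rnorm(N * 4L * OH * OH), N)
  f <- function(X, W, b) {
    sum(hvem:::conv2d_forward_cpp(X, W, b, C, H, H, K, S, P) * R)
  }
  bk <- hvem:::conv2d_backward_cpp(X, W, R, C, H, H, K, S, P, TRUE)
  eps <- 1e-6
  for (i in sample(length(W), 10L)) {
    Wp <- W; Wp[i] <- Wp[i] + eps; Wm <- W; Wm[i] <- Wm[i] - eps
    expect_equal(bk$dW[i], (f(X, Wp, b) - f(X, Wm, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in sample(length(X), 10L)) {
    Xp <- X; Xp[i] <- Xp[i] + eps; Xm <- X; Xm[i] <- Xm[i] - eps
    expect_equal(bk$dX[i], (f(Xp, W, b) - f(Xm, W, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})
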