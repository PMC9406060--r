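test_that("gabor kernels match direct evaluation of the closed form", {
  p <- gabor_params(1, theta = 0, lambda = 4, sigma = 2, gamma = 1, psi = 0)
  k <- build_gabor_kernels(p, 9L)
  expect_equal(dim(k), c(2L, 1L, 9L, 9L))
  # centre pixel of the even kernel is exp(0)*cos(psi) = 1
  expect_equal(k[1, 1, 5, 5], 1)
  # at (x = 2, y = 0): exp(-0.5) * cos(pi)
  expect_equal(k[1, 1, 5, 7], exp(-0.5) * cos(pi), tolerance = 1e-12)
  # odd kernel vanishes at the origin for psi = 0
  expect_equal(k[2, 1, 5, 5], 0, tolerance = 1e-15)
})

test_that("gabor bank equals the pointwise oracle for random parameter tuples", {
  set.seed(101)
  n <- 100L
  p <- gabor_params(n,
                    theta = runif(n, 0, 2 * pi),
                    lambda = runif(n, 1, 12),
                    sigma = runif(n, 0.5, 6),
                    gamma = runif(n, 0.2, 3),
                    psi = runif(n, -pi, pi))
  k <- build_gabor_kernels(p, 9L)
  worst <- 0
  for (i in seq_len(n)) {
    for (iy in 1:9) {
      for (ix in 1:9) {
        x <- ix - 5; y <- iy - 5
        re <- gabor_point_oracle(x, y, p$theta[i], p$lambda[i], p$sigma[i],
                                 p$gamma[i], p$psi[i])
        im <- gabor_point_oracle(x, y, p$theta[i], p$lambda[i], p$sigma[i],
                                 p$gamma[i], p$psi[i] + pi / 2)
        worst <- max(worst, abs(k[i, 1, iy, ix] - re),
                     abs(k[n + i, 1, iy, ix] - im))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("even kernels are invariant under a half-turn of orientation", {
  p1 <- gabor_params(3, theta = c(0.3, 1.1, 2.0), lambda = c(3, 5, 8))
  p2 <- gabor_params(3, theta = c(0.3, 1.1, 2.0) + pi, lambda = c(3, 5, 8))
  k1 <- build_gabor_kernels(p1, 9L)
  k2 <- build_gabor_kernels(p2, 9L)
  expect_equal(k1[1:3, , , ], k2[1:3, , , ], tolerance = 1e-12)
})

test_that("parameter-domain violations are rejected", {
  expect_error(gabor_params(2, lambda = c(3, -1)), "lambda")
  expect_error(gabor_params(2, sigma = c(0, 1)), "sigma")
  expect_error(gabor_params(2, gamma = c(1, -2)), "gamma")
  expect_error(build_gabor_kernels(gabor_params(2), size = 8L), "odd")
})

test_that("analytic parameter gradients agree with central differences", {
  set.seed(11)
  p <- gabor_params(4, theta = runif(4, 0, pi), lambda = runif(4, 2, 8),
                    sigma = runif(4, 1, 4), gamma = runif(4, 0.5, 2),
                    psi = runif(4, -1, 1))
  gb <- hvem:::gabor_bank(p, 9L, grads = TRUE)
  eps <- 1e-6
  for (par in c("theta", "lambda", "sigma", "gamma", "psi")) {
    for (i in c(1L, 3L)) {
      pp <- p; pp[[par]][i] <- pp[[par]][i] + eps
      pm <- p; pm[[par]][i] <- pm[[par]][i] - eps
      num <- (hvem:::gabor_bank(pp, 9L)$weights -
              hvem:::gabor_bank(pm, 9L)$weights) / (2 * eps)
      rows <- c(i, 4L + i)  # even and odd kernels of tuple i
      expect_equal(gb$grads[[par]][rows, ], num[rows, ], tolerance = 1e-6)
    }
  }
})
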