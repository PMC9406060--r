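test_that("ridge fits match the normal-equations oracle", {
  set.seed(33)
  X <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rnorm(10), 5, 2)
  for (lam in c(0.5, 10)) {
    f <- hvem:::ridge_fit(X, Y, lam)
    # brute-force oracle on centred data
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    W_oracle <- solve(t(Xc) %*% Xc + lam * diag(3)) %*% t(Xc) %*% Yc
    expect_equal(f$W, W_oracle, tolerance = 1e-10)
  }
  # dual path (D > N) agrees with the primal formula
  Xw <- matrix(rnorm(40), 4, 10)
  Yw <- matrix(rnorm(8), 4, 2)
  f <- hvem:::ridge_fit(Xw, Yw, 2)
  Xc <- sweep(Xw, 2, colMeans(Xw)); Yc <- sweep(Yw, 2, colMeans(Yw))
  W_oracle <- solve(t(Xc) %*% Xc + 2 * diag(10)) %*% t(Xc) %*% Yc
  expect_equal(f$W, W_oracle, tolerance = 1e-10)
})

test_that("ridge limits behave: lambda -> 0 interpolates, lambda -> Inf shrinks to the mean", {
  f <- hvem:::ridge_fit(matrix(c(1, 2), 2, 1), matrix(c(1, 2), 2, 1), 1e-10)
  expect_equal(f$W[1, 1], 1, tolerance = 1e-6)
  expect_equal(as.numeric(hvem:::ridge_predict(f, matrix(c(1, 2), 2, 1))),
               c(1, 2), tolerance = 1e-6)

  set.seed(43)
  X <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(20), 10, 2)
  f_big <- hvem:::ridge_fit(X, Y, 1e9)
  expect_lt(max(abs(f_big$W)), 1e-6)
  expect_equal(hvem:::ridge_predict(f_big, X),
               matrix(colMeans(Y), 10, 2, byrow = TRUE), tolerance = 1e-6)

  # coefficient norm decreases monotonically in lambda
  norms <- vapply(c(0.1, 1, 10, 100), function(l) {
    sum(hvem:::ridge_fit(X, Y, l)$W^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("rank-deficient designs at lambda = 0 produce an advisory error", {
  X <- cbind(1:6, 1:6)  # duplicated column
  Y <- matrix(rnorm(6), 6, 1)
  expect_error(ridge_encode(list(l1 = X), list(l1 = X), Y, Y, lambdas = 0),
               "lambda > 0")
})

test_that("ridge encoding selects the informative layer", {
  set.seed(53)
  n <- 60L
  good <- matrix(rnorm(n * 5), n)
  Y <- good %*% matrix(rnorm(15), 5, 3) + 0.1 * matrix(rnorm(n * 3), n)
  noise <- matrix(rnorm(n * 5), n)
  tr <- 1:40; va <- 41:60
  enc <- ridge_encode(list(noise = noise[tr, ], good = good[tr, ]),
                      list(noise = noise[va, ], good = good[va, ]),
                      Y[tr, ], Y[va, ])
  expect_equal(enc$selected$layer, "good")
  expect_gt(mean(enc$val_accuracy$rho), 0.8)
  # selection is reproducible for fixed features
  enc2 <- ridge_encode(list(noise = noise[tr, ], good = good[tr, ]),
                       list(noise = noise[va, ], good = good[va, ]),
                       Y[tr, ], Y[va, ])
  expect_identical(enc$selected, enc2$selected)
  expect_error(ridge_encode(list(a = good[tr, ], a = noise[tr, ]),
                            list(a = good[va, ], a = noise[va, ]),
                            Y[tr, ], Y[va, ]), "uniquely named")
})

test_that("the random feature extractor yields 7 deterministic layers", {
  ex <- random_feature_extractor(32L, seed = 6L)
  X <- generate_stimuli(4, side = 32L, seed = 8L)
  f1 <- ex(X)
  expect_named(f1, c("pool1", "pool2", "pool3", "pool4", "pool5", "fc6", "fc7"))
  expect_true(all(vapply(f1, nrow, integer(1)) == 4L))
  ex2 <- random_feature_extractor(32L, seed = 6L)
  expect_identical(f1, ex2(X))
  expect_error(ex(matrix(0, 2, 100)), "built for side")
})
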