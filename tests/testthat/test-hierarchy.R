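test_that("effective-voxel selection uses a strict threshold and keeps order", {
  expect_equal(select_effective_voxels(c(0.5, 0.1, 0.28), 0.27), c(1L, 3L))
  # exactly at the threshold is excluded (strict inequality)
  expect_equal(select_effective_voxels(c(0.27, 0.5), 0.27), 2L)
  expect_error(select_effective_voxels(c(0.1, 0.2), 0.27), "no voxel")
})

test_that("raising the selection threshold never adds voxels", {
  set.seed(31)
  for (rep in 1:20) {
    rho <- runif(50, -0.2, 0.9)
    th <- sort(runif(2, 0, 0.8))
    lo <- tryCatch(select_effective_voxels(rho, th[1]), error = function(e) integer(0))
    hi <- tryCatch(select_effective_voxels(rho, th[2]), error = function(e) integer(0))
    expect_true(all(hi %in% lo))
  }
})

test_that("hierarchical readout forward matches hand evaluation", {
  w <- list(mode = "nonlinear", W1 = matrix(c(1, 1), 2, 1), b1 = -1,
            W2 = matrix(2, 1, 1), b2 = 0)
  expect_equal(hier_readout_forward(matrix(c(2, 1), 1), w)[1, 1], 4)
  expect_equal(hier_readout_forward(matrix(c(0, 0), 1), w)[1, 1], 0)
  # all-zero weights -> output is the second bias
  w0 <- list(mode = "nonlinear", W1 = matrix(0, 2, 3), b1 = rep(0, 3),
             W2 = matrix(0, 3, 2), b2 = c(5, -1))
  expect_equal(as.numeric(hier_readout_forward(matrix(1, 1, 2), w0)), c(5, -1))
  # latent width defaults to the target voxel count
  ro <- hier_readout_init(10L, 1535L, seed = 1L)
  expect_equal(ncol(ro$W1), 1535L)
  expect_error(hier_readout_forward(matrix(0, 1, 3), w), "width mismatch")
})

test_that("the squared-weight rule gates gradients by w^2 exactly", {
  expect_equal(apply_squared_weight_rule(0.1, 2), 0.4)
  expect_equal(apply_squared_weight_rule(5, 0), 0)
  g <- matrix(rnorm(12), 3)
  W <- matrix(sample(c(-1, 1), 12, replace = TRUE), 3)
  expect_equal(apply_squared_weight_rule(g, W), g)   # unit gate
  expect_equal(apply_squared_weight_rule(g, 2 * W), 4 * g)
  expect_error(apply_squared_weight_rule(matrix(0, 2, 2), matrix(0, 3, 2)),
               "shapes differ")
})

test_that("update magnitudes are monotone in |w| and unit-weight steps match plain descent", {
  set.seed(41)
  g <- 0.3
  ws <- seq(0.1, 3, by = 0.1)
  mags <- abs(vapply(ws, function(w) apply_squared_weight_rule(g, w), numeric(1)))
  expect_true(all(diff(mags) > 0))

  # per-step equivalence: from any |w| = 1 state, one rule-gated descent step
  # equals one plain gradient-descent step to 1e-10
  lr <- 0.05
  for (rep in 1:5) {
    W1 <- matrix(sample(c(-1, 1), 8, replace = TRUE), 4, 2)
    X <- matrix(rnorm(12), 3, 4)
    y <- matrix(rnorm(6), 3, 2)
    grad <- crossprod(X, (X %*% W1 - y)) / 3
    plain <- W1 - lr * grad
    gated <- W1 - lr * apply_squared_weight_rule(grad, W1)
    expect_equal(gated, plain, tolerance = 1e-10)
  }
})

test_that("representation extraction freezes the encoder and restricts columns", {
  ds <- tiny_h0()
  cfg <- fast_config()
  m <- train_stage1(ds, "V1", cfg, epochs = 2L)
  before <- m$weights

  rep_f <- extract_representation(m, ds$stimuli$val, "feature")
  expect_equal(dim(rep_f), c(30L, backbone_spec(32L)$n_features))
  expect_identical(m$weights, before)

  sel <- c(2L, 5L, 9L)
  rep_v <- extract_representation(m, ds$stimuli$val, "voxel", selected = sel)
  expect_equal(dim(rep_v), c(30L, 3L))
  expect_equal(unclass(rep_v), predict(m, ds$stimuli$val)[, sel],
               ignore_attr = TRUE)
  expect_error(extract_representation(m, ds$stimuli$val, "voxel"),
               "requires `selected`")

  # frozen weights make repeated extraction identical
  expect_identical(unclass(rep_f),
                   unclass(extract_representation(m, ds$stimuli$val, "feature")))
})
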