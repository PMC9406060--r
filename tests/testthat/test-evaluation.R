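test_that("pearson accuracy matches hand values and flags degenerate voxels", {
  acc <- pearson_accuracy(cbind(c(1, 2, 3, 4)), cbind(c(2, 1, 4, 3)))
  expect_equal(acc$rho, 0.6)
  x <- matrix(rnorm(20), 10)
  expect_equal(pearson_accuracy(x, x)$rho, c(1, 1))
  # constant predicted column -> undefined, excluded downstream
  acc <- pearson_accuracy(matrix(rnorm(15), 5), cbind(rnorm(5), 1, rnorm(5)))
  expect_equal(acc$defined, c(TRUE, FALSE, TRUE))
  expect_true(is.na(acc$rho[2]))
  expect_error(pearson_accuracy(matrix(0, 4, 2), matrix(0, 4, 3)),
               "shape mismatch")
  expect_error(pearson_accuracy(matrix(0, 2, 2), matrix(0, 2, 2)),
               "at least 3")
})

test_that("pearson accuracy equals a two-pass covariance oracle to 1e-12", {
  set.seed(51)
  m <- matrix(rnorm(200), 20)
  p <- matrix(rnorm(200), 20)
  acc <- pearson_accuracy(m, p)
  for (v in seq_len(ncol(m))) {
    # textbook two-pass oracle, scalar arithmetic only
    mb <- mean(m[, v]); pb <- mean(p[, v])
    cv <- 0; vm <- 0; vp <- 0
    for (i in seq_len(nrow(m))) {
      cv <- cv + (m[i, v] - mb) * (p[i, v] - pb)
      vm <- vm + (m[i, v] - mb)^2
      vp <- vp + (p[i, v] - pb)^2
    }
    expect_equal(acc$rho[v], cv / sqrt(vm * vp), tolerance = 1e-12)
  }
})

test_that("permutation threshold is seeded, symmetric at alpha = 0.5, and excludes undefined voxels", {
  set.seed(61)
  m <- matrix(rnorm(30 * 40), 30)
  p <- matrix(rnorm(30 * 40), 30)
  th1 <- permutation_threshold(m, p, n_perm = 300L, alpha = 0.5, seed = 9L)
  th2 <- permutation_threshold(m, p, n_perm = 300L, alpha = 0.5, seed = 9L)
  expect_identical(th1$global, th2$global)
  expect_lt(abs(th1$global), 0.06)  # median of a null symmetric about 0
  m2 <- m; m2[, 3] <- 1
  th3 <- permutation_threshold(m2, p, n_perm = 50L, alpha = 0.1, seed = 1L)
  expect_true(is.na(th3$per_voxel[3]))
})

test_that("top-k average accuracy follows its contract", {
  expect_equal(topk_average_accuracy(c(0.9, 0.5, 0.1), k = 2), 0.7)
  expect_equal(suppressWarnings(topk_average_accuracy(c(0.9, 0.5, 0.1), k = 300)),
               0.5)
  expect_warning(topk_average_accuracy(c(0.9, 0.5, 0.1), k = 5), "averaging all")
  expect_equal(topk_average_accuracy(c(NA, 0.4, 0.8, NA), k = 2), 0.6)
  expect_error(topk_average_accuracy(c(NA_real_, NA_real_), k = 1), "no voxel")
})

test_that("advantage analysis enumerates joint-valid voxels and handles ties", {
  a <- advantage_analysis(c(0.5, 0.4, 0.3), c(0.4, 0.5, 0.28),
                          threshold = 0.27, n_perm = 200L, seed = 2L)
  expect_equal(a$n_joint, 3L)
  expect_equal(a$prop_a, 2 / 3)
  expect_equal(a$prop_b, 1 / 3)

  ident <- advantage_analysis(c(0.5, 0.6), c(0.5, 0.6), threshold = 0.27,
                              n_perm = 50L, seed = 2L)
  expect_equal(ident$n_tied, 2L)
  expect_true(is.na(ident$prop_a))

  expect_error(advantage_analysis(c(0.1, 0.2), c(0.1, 0.2), threshold = 0.27),
               "no voxel")
})

test_that("advantage proportions of (A,B) and (B,A) are complementary", {
  set.seed(71)
  for (rep in 1:10) {
    ra <- runif(40, 0.28, 0.9)
    rb <- runif(40, 0.28, 0.9)
    ab <- advantage_analysis(ra, rb, threshold = 0.27, n_perm = 20L, seed = 1L)
    ba <- advantage_analysis(rb, ra, threshold = 0.27, n_perm = 20L, seed = 1L)
    expect_equal(ab$prop_a + ba$prop_a, 1)
  }
})

test_that("best-encoded proportions use at-least-one-valid inclusion and sum to 1", {
  p <- best_encoded_proportions(list(A = c(0.5, 0.1), B = c(0.3, 0.4)),
                                threshold = 0.27)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  # voxel 1 valid only under A, voxel 2 only under B: both included
  expect_equal(attr(p, "n_included"), 2L)

  expect_equal(as.numeric(best_encoded_proportions(list(only = c(0.4, 0.9)),
                                                   threshold = 0.27)), 1)
  expect_error(best_encoded_proportions(list(A = c(0.1), B = c(0.2)),
                                        threshold = 0.27), "no voxel")

  set.seed(81)
  models <- list(m1 = runif(30, 0, 0.8), m2 = runif(30, 0, 0.8),
                 m3 = runif(30, 0, 0.8))
  p1 <- best_encoded_proportions(models, threshold = 0.27)
  expect_equal(sum(p1), 1)
  perm <- c("m3", "m1", "m2")
  p2 <- best_encoded_proportions(models[perm], threshold = 0.27)
  expect_equal(as.numeric(p2[names(p1)]), as.numeric(p1))
})
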