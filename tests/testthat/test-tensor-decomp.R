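test_that("space-by-time NMF is exact on noiseless rank-(1,1) data", {
  ft <- factor_tensor(s = 8, t = 6, n = 5, p = 1, l = 1, seed = 1)
  fit <- space_by_time_nmf(ft$tensor, 1, 1, n_restarts = 2, seed = 2)
  expect_lt(fit$reconstruction_error / sum(ft$tensor$counts^2), 1e-6)
  expect_true(all(fit$core >= 0))
  expect_true(all(fit$temporal_modules >= 0))
  expect_true(all(fit$spatial_modules >= 0))
})

test_that("space-by-time NMF objective is non-increasing and modules are normalized", {
  tt <- tiny_tensor(s = 15, t = 7, n = 6, seed = 3)
  fit <- space_by_time_nmf(tt, 3, 2, n_restarts = 1, seed = 4, max_iter = 120)
  tr <- attr(fit, "trace")
  expect_true(all(diff(tr) <= 1e-8 * max(tr)))
  expect_equal(colSums(fit$temporal_modules^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(rowSums(fit$spatial_modules^2), rep(1, 2), tolerance = 1e-10)
  # normalization left the reconstruction error unchanged
  expect_equal(reconstruction_error(fit, tt), fit$reconstruction_error,
               tolerance = 1e-8)
  zero <- trial_tensor(array(0, c(3, 2, 2)), 10, c(0, 20), rep("a", 3))
  expect_error(space_by_time_nmf(zero, 1, 1), "all-zero")
  expect_error(space_by_time_nmf(tt, 0, 1), "integer >= 1")
})

test_that("orthogonal Tucker-2 has orthonormal factors and exact core recovery", {
  ft <- factor_tensor(s = 10, t = 6, n = 5, p = 2, l = 2, seed = 5)
  fit <- orthogonal_tucker2(ft$tensor, 2, 2)
  expect_lt(max(abs(crossprod(fit$temporal_modules) - diag(2))), 1e-8)
  expect_lt(max(abs(tcrossprod(fit$spatial_modules) - diag(2))), 1e-8)
  # data generated from rank-(2,2) factors are reconstructed exactly
  expect_lt(fit$reconstruction_error / sum(ft$tensor$counts^2), 1e-10)
  # inference on training data reproduces the fitted core (orthonormal projection)
  h <- infer_core(fit, ft$tensor)
  expect_equal(h, fit$core, tolerance = 1e-10)
})

test_that("full-rank orthogonal Tucker-2 reconstructs any tensor to machine precision", {
  tt <- tiny_tensor(s = 6, t = 4, n = 3, seed = 6)
  fit <- orthogonal_tucker2(tt, 4, 3)
  expect_lt(fit$reconstruction_error / sum(tt$counts^2), 1e-10)
})

test_that("alternation reaches the many-restart best fit on a tiny tensor", {
  tt <- tiny_tensor(s = 3, t = 3, n = 3, seed = 7)
  fit <- orthogonal_tucker2(tt, 2, 2)
  # oracle: restart the same alternation from many random orthonormal inits
  set.seed(8)
  best <- Inf
  for (r in 1:20) {
    bt <- qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2]
    bs <- t(qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2])
    for (it in 1:50) {
      z1 <- unfold_tall(tt$counts) %*% t(bs)
      m1 <- matrix(array(z1, c(3, 3, 2)), 3, 6)
      bt <- svd(m1, nu = 2)$u[, 1:2]
      x <- crossprod(bt, unfold_wide(tt$counts))
      m2 <- matrix(aperm(array(x, c(2, 3, 3)), c(1, 3, 2)), 6, 3)
      bs <- t(svd(m2, nv = 2)$v[, 1:2])
    }
    h <- project_core(tt$counts, bt, bs)
    best <- min(best, sum(tt$counts^2) - sum(h^2))
  }
  expect_lt(fit$reconstruction_error, best + 1e-6 * sum(tt$counts^2))
})

test_that("frozen-factor core inference cannot beat the joint fit; zero trials give zero cores", {
  tt <- tiny_tensor(s = 12, t = 6, n = 5, seed = 9)
  fit <- space_by_time_nmf(tt, 2, 2, n_restarts = 2, seed = 10)
  h <- infer_core(fit, tt, seed = 11)
  expect_gte(reconstruction_error(fit, tt, core = h),
             fit$reconstruction_error * (1 - 1e-8))
  # a zero trial yields a zero core slice after one multiplicative update
  ztrial <- trial_tensor(array(0, c(1, 6, 5)), 10, c(0, 60), "z")
  hz <- infer_core(fit, ztrial, max_iter = 1, seed = 12)
  expect_equal(max(abs(hz)), 0)
  bad <- tiny_tensor(s = 2, t = 5, n = 5)
  expect_error(infer_core(fit, bad), "do not match")
})

test_that("reconstruction error equals the brute-force residual sum and is monotone in noise", {
  ft <- factor_tensor(s = 5, t = 4, n = 3, p = 2, l = 2, seed = 13)
  fit <- orthogonal_tucker2(ft$tensor, 2, 2)
  # brute force elementwise
  err <- 0
  for (s in 1:5) {
    hs <- matrix(fit$core[s, , ], 2, 2)
    rec <- fit$temporal_modules %*% hs %*% fit$spatial_modules
    err <- err + sum((ft$tensor$counts[s, , ] - rec)^2)
  }
  expect_equal(reconstruction_error(fit, ft$tensor), err, tolerance = 1e-10)
  # perfect factorization -> 0; added perturbations increase the error
  expect_lt(err / sum(ft$tensor$counts^2), 1e-10)
  errs <- vapply(c(0.1, 0.5, 1), function(sdv) {
    set.seed(14)
    noisy <- ft$tensor
    noisy$counts <- noisy$counts + array(abs(rnorm(60, sd = sdv)), dim = c(5, 4, 3))
    reconstruction_error(fit, noisy)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("NMF module sets are stable across restarts relative to random sets", {
  pats <- make_block_patterns("separable")
  tens <- generate_trials(pats, n_trials = 120, seed = 15)
  fits <- lapply(1:4, function(r) {
    space_by_time_nmf(tens, 2, 2, n_restarts = 1, seed = 100 + r)
  })
  pair_sims <- utils::combn(4, 2, function(ij) {
    module_set_similarity(fits[[ij[1]]], fits[[ij[2]]])
  })
  set.seed(16)
  rand_sims <- replicate(6, {
    a <- lapply(1:4, function(i) matrix(runif(600), 30, 20))
    b <- lapply(1:4, function(i) matrix(runif(600), 30, 20))
    module_set_similarity(a, b)
  })
  expect_gt(mean(pair_sims), mean(rand_sims))
})
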