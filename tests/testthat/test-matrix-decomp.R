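test_that("spatiotemporal NMF factorizes rank-1 data exactly with monotone error", {
  ft <- factor_tensor(s = 8, t = 5, n = 4, p = 1, l = 1, seed = 1)
  fit <- spatiotemporal_nmf(ft$tensor, 1, n_restarts = 2, seed = 3)
  total <- sum(ft$tensor$counts^2)
  expect_lt(fit$reconstruction_error / total, 1e-6)
  tr <- attr(fit, "trace")
  expect_true(all(diff(tr) <= 1e-8 * max(tr)))
  expect_true(all(fit$activations >= 0))
  expect_true(all(vapply(fit$modules, function(m) all(m >= 0), logical(1))))
})

test_that("NMF error decreases monotonically on arbitrary data", {
  tt <- tiny_tensor(s = 12, t = 6, n = 5, seed = 7)
  fit <- spatiotemporal_nmf(tt, 3, n_restarts = 1, seed = 11, max_iter = 100)
  tr <- attr(fit, "trace")
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) <= 1e-8 * max(tr)))
  zero <- trial_tensor(array(0, c(3, 2, 2)), 10, c(0, 20), rep("a", 3))
  expect_error(spatiotemporal_nmf(zero, 1), "all-zero")
})

test_that("NMF with a fixed seed is bit-reproducible", {
  tt <- tiny_tensor(s = 10, t = 5, n = 4, seed = 8)
  f1 <- spatiotemporal_nmf(tt, 2, n_restarts = 2, seed = 5)
  f2 <- spatiotemporal_nmf(tt, 2, n_restarts = 2, seed = 5)
  expect_identical(f1$modules, f2$modules)
  expect_identical(f1$activations, f2$activations)
  sb1 <- space_by_time_nmf(tt, 2, 2, n_restarts = 2, seed = 5)
  sb2 <- space_by_time_nmf(tt, 2, 2, n_restarts = 2, seed = 5)
  expect_identical(sb1$core, sb2$core)
})

test_that("PCA modules are orthonormal and the error equals discarded eigenvalues", {
  tt <- tiny_tensor(s = 20, t = 4, n = 3, seed = 9)
  k <- 3
  fit <- spatiotemporal_linear(tt, k, "pca")
  B <- do.call(rbind, lapply(fit$modules, as.vector))
  # rows reshaped from T x N modules are orthonormal
  Bv <- do.call(rbind, lapply(fit$modules, function(m) as.vector(t(m))))
  expect_lt(max(abs(tcrossprod(Bv) - diag(k))), 1e-10)
  # eigen-decomposition oracle for the reconstruction error
  X <- scale(matricize_spatiotemporal(tt), scale = FALSE)
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$reconstruction_error, sum(ev[-seq_len(k)]), tolerance = 1e-8)
})

test_that("ICA and FA satisfy their contracts on latent-structure data", {
  # two mutually independent non-Gaussian modules over 300 cells, mixed
  # across 80 trials: the spatial-ICA model the decomposition assumes
  set.seed(10)
  d <- 300
  b1 <- rexp(d) * (runif(d) < 0.2)
  b2 <- rexp(d) * (runif(d) < 0.2)
  h <- matrix(rnorm(80 * 2), 80, 2)
  x <- h %*% rbind(b1, b2) + matrix(rnorm(80 * d, sd = 0.02), 80, d)
  # a constant offset keeps counts non-negative and is removed by centering
  tt <- tensorize_spatiotemporal(x - min(x), 30, 10, labels = rep("z", 80))
  ica <- spatiotemporal_linear(tt, 2, "ica", seed = 1)
  expect_length(ica$modules, 2)
  expect_equal(dim(ica$activations), c(80, 2))
  # ICA components are mean-removed; assess recovery by centered correlation
  cors <- sapply(ica$modules, function(m) {
    c(abs(cor(as.vector(t(m)), b1)), abs(cor(as.vector(t(m)), b2)))
  })
  expect_gt(max(cors[1, ]), 0.98)
  expect_gt(max(cors[2, ]), 0.98)

  fa <- spatiotemporal_linear(tt, 2, "fa", seed = 2)
  expect_length(fa$modules, 2)
  # unit-norm modules with scales absorbed into activations
  expect_equal(vapply(fa$modules, function(m) sqrt(sum(m^2)), numeric(1)),
               rep(1, 2), tolerance = 1e-8)
  # FA captures the 2-factor structure: residual far below total variance
  rel_fa <- fa$reconstruction_error / sum(scale(x - min(x), scale = FALSE)^2)
  expect_lt(rel_fa, 0.2)
})

test_that("space-only decomposition equals the method applied to the spatial matricization", {
  tt <- tiny_tensor(s = 8, t = 6, n = 5, seed = 12)
  sp <- space_only_decomposition(tt, 2, "pca")
  # oracle: PCA run directly on the (S*T) x N matrix
  X <- scale(matricize_spatial(tt), scale = FALSE)
  sv <- svd(X, nu = 2, nv = 2)
  oracle_mods <- t(sv$v)
  for (i in 1:2) {
    expect_equal(abs(sum(sp$spatial_modules[i, ] * oracle_mods[i, ])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(dim(sp$activations), c(8, 6, 2))

  # single active neuron, NMF -> module concentrated on that neuron
  counts <- array(0, c(10, 4, 3))
  counts[, , 2] <- matrix(rpois(40, 5), 10, 4)
  solo <- trial_tensor(counts, 10, c(0, 40), rep("a", 10))
  nf <- space_only_decomposition(solo, 1, "nmf", seed = 1)
  w <- nf$spatial_modules[1, ] / sum(nf$spatial_modules[1, ])
  expect_gt(w[2], 0.99)
})

test_that("frozen-module inference projects correctly and cannot beat the joint fit", {
  ft <- factor_tensor(s = 10, t = 5, n = 4, p = 2, l = 2, seed = 13)
  tt <- ft$tensor
  fit <- spatiotemporal_nmf(tt, 2, n_restarts = 2, seed = 4)
  # a new trial equal to module 1 gets activation ~ (c, 0)
  new <- trial_tensor(array(fit$modules[[1]], c(1, 5, 4)), 10, c(0, 50), "a")
  h <- infer_activations(fit, new, seed = 1)
  expect_gt(h[1, 1] / (sum(h) + 1e-12), 0.99)

  # PCA inference equals inner products with the orthonormal modules
  pfit <- spatiotemporal_linear(tt, 2, "pca")
  hp <- infer_activations(pfit, tt)
  X <- sweep(matricize_spatiotemporal(tt), 2, pfit$center)
  Bv <- do.call(rbind, lapply(pfit$modules, function(m) as.vector(t(m))))
  expect_equal(hp, X %*% t(Bv), tolerance = 1e-8)

  # frozen-module NMF error on the same data >= jointly fitted error
  h_frozen <- infer_activations(fit, tt, seed = 2)
  err_frozen <- reconstruction_error(fit, tt, activations = h_frozen)
  expect_gte(err_frozen, fit$reconstruction_error - 1e-8 * fit$reconstruction_error - 1e-10)
})
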