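#' Spatiotemporal decomposition result
#'
#' Represents the matrix model `r^s(t) = sum_k h_k^s b_k(t) + residual`:
#' `K` trial-invariant spatiotemporal modules (each `T x N`) combined on each
#' trial by scalar activation coefficients.
#'
#' @param modules list of `K` matrices `T x N`.
#' @param activations `S x K` coefficient matrix.
#' @param method method tag (`"nmf"`, `"pca"`, `"ica"`, `"fa"`).
#' @param reconstruction_error summed squared reconstruction residual.
#' @param center optional `T * N` column-mean vector (centered methods).
#' @param iterations iterations used by the winning run.
#' @return object of class `st_decomp`.
#' @keywords internal
new_st_decomp <- function(modules, activations, method, reconstruction_error,
                          center = NULL, iterations = NA_integer_) {
  structure(
    list(
      modules = modules, activations = activations, method = method,
      reconstruction_error = reconstruction_error, center = center,
      iterations = iterations
    ),
    class = "st_decomp"
  )
}

#' @export
print.st_decomp <- function(x, ...) {
  d <- dim(x$modules[[1]])
  cat(sprintf(
    "<st_decomp/%s> %d modules (%d bins x %d neurons), %d trials, error %.4g\n",
    x$method, length(x$modules), d[1], d[2], nrow(x$activations),
    x$reconstruction_error
  ))
  invisible(x)
}

# Multiplicative-update NMF for R ~ H B (Euclidean objective).
# Returns factors, the error trace (monotone non-increasing) and iterations.
nmf_mu <- function(R, k, max_iter = 500, tol = 1e-6,
                   H = NULL, B = NULL, update_b = TRUE) {
  s <- nrow(R)
  d <- ncol(R)
  if (is.null(H)) H <- matrix(runif(s * k), s, k)
  if (is.null(B)) B <- matrix(runif(k * d), k, d)
  total <- frobenius_sq(R)
  errs <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (R %*% t(B)) / (H %*% tcrossprod(B) + .mu_eps)
    if (update_b) {
      B <- B * (crossprod(H, R)) / (crossprod(H) %*% B + .mu_eps)
    }
    err <- frobenius_sq(R - H %*% B)
    errs <- c(errs, err)
    if (is.finite(prev) && (prev - err) < tol * max(prev, .mu_eps)) break
    prev <- err
  }
  list(H = H, B = B, error = err, trace = errs, iterations = it, total = total)
}

#' Spatiotemporal non-negative matrix factorization
#'
#' Factorizes the `S x (T * N)` trial matricization as `R ~ H B` with
#' non-negative activations `H` (`S x K`) and modules `B` (`K x (T * N)`),
#' using Lee-Seung multiplicative updates for the Euclidean norm. The
#' reconstruction error is non-increasing across iterations; the best of
#' `n_restarts` uniformly-initialized runs is returned. Modules are reshaped
#' to `T x N` and scaled to unit norm with scales absorbed into `H`.
#'
#' @param tensor a [trial_tensor()].
#' @param k number of modules, `1 <= k <= min(S, T * N)`.
#' @param max_iter,tol stopping rule: stop when the relative error decrease
#'   falls below `tol` or after `max_iter` iterations.
#' @param n_restarts number of random restarts (lowest final error wins).
#' @param seed RNG seed for reproducible initializations.
#' @return an `st_decomp` with `method = "nmf"`. The error trace of the
#'   winning run is attached as attribute `"trace"`.
#' @export
spatiotemporal_nmf <- function(tensor, k, max_iter = 500, tol = 1e-6,
                               n_restarts = 5, seed = NULL) {
  k <- assert_scalar_count(k, "k")
  R <- matricize_spatiotemporal(tensor)
  if (sum(R) == 0) abort("all-zero input: NMF updates are undefined.")
  if (k > min(nrow(R), ncol(R))) abort("`k` exceeds min(S, T * N).")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seeds[[r]], nmf_mu(R, k, max_iter, tol))
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  # unit-norm modules, scales into activations
  norms <- sqrt(rowSums(best$B^2))
  keep <- norms > 0
  best$B[keep, ] <- best$B[keep, , drop = FALSE] / norms[keep]
  best$H[, keep] <- sweep(best$H[, keep, drop = FALSE], 2, norms[keep], `*`)
  mods <- lapply(seq_len(k), function(i) {
    row_to_module(best$B[i, ], n_bins(tensor), n_neurons(tensor))
  })
  out <- new_st_decomp(mods, best$H, "nmf", best$error,
                       iterations = best$iterations)
  attr(out, "trace") <- best$trace
  out
}

#' Spatiotemporal linear decompositions (PCA, ICA, FA)
#'
#' Applies a statistically constrained linear factorization to the
#' `S x (T * N)` trial matricization: PCA yields orthonormal modules ordered
#' by decreasing explained variance; ICA (Hyvarinen's fixed-point iteration
#' with a logcosh contrast and symmetric decorrelation) yields maximally
#' non-Gaussian modules; FA (expectation-maximization with per-variable
#' Gaussian noise) yields latent-factor loadings as modules with posterior
#' factor means as activations. ICA and FA modules are normalized to unit
#' norm with scales absorbed into the activations. These methods center the
#' data; the column means are kept in the result (`$center`).
#'
#' @inheritParams spatiotemporal_nmf
#' @param method `"pca"`, `"ica"` or `"fa"`.
#' @param k number of modules, `k <= min(S - 1, T * N)`.
#' @param max_iter,tol iteration controls for ICA/FA.
#' @return an `st_decomp`.
#' @export
spatiotemporal_linear <- function(tensor, k, method = c("pca", "ica", "fa"),
                                  seed = NULL, max_iter = 200, tol = 1e-6) {
  method <- match.arg(method)
  R <- matricize_spatiotemporal(tensor)
  fit <- linear_decomposition(R, k, method, seed, max_iter, tol)
  mods <- lapply(seq_len(k), function(i) {
    row_to_module(fit$B[i, ], n_bins(tensor), n_neurons(tensor))
  })
  new_st_decomp(mods, fit$H, method, fit$error, center = fit$center)
}

# Shared engine for PCA/ICA/FA on a generic data matrix R (rows = samples).
linear_decomposition <- function(R, k, method, seed = NULL,
                                 max_iter = 200, tol = 1e-6) {
  k <- assert_scalar_count(k, "k")
  if (k > min(nrow(R) - 1L, ncol(R))) {
    abort("`k` exceeds min(S - 1, number of features).")
  }
  center <- colMeans(R)
  X <- sweep(R, 2, center)
  if (method == "pca") {
    sv <- svd(X, nu = k, nv = k)
    if (k > sum(sv$d > 1e-12)) abort("`k` exceeds the data rank.")
    B <- t(sv$v)                      # k x d, orthonormal rows
    H <- X %*% sv$v                   # scores
    err <- frobenius_sq(X) - sum(sv$d[seq_len(k)]^2)
    return(list(B = B, H = H, error = max(err, 0), center = center))
  }
  if (method == "ica") {
    # module-independent orientation: the modules are the sources, assumed
    # mutually independent (and non-Gaussian) as functions over the T*N
    # cells; trials are the observed mixtures. Overlapping ground-truth
    # patterns violate this assumption, which is the point of the contract.
    fit <- with_seed(seed, fastica_fixed_point(t(X), k, max_iter, tol))
    B <- t(fit$H)                 # k x d modules (sources over cells)
    norms <- sqrt(rowSums(B^2))
    keep <- norms > 0
    B[keep, ] <- B[keep, , drop = FALSE] / norms[keep]
    H <- t(solve(tcrossprod(B), B %*% t(X)))   # least-squares activations
    return(list(B = B, H = H, error = frobenius_sq(X - H %*% B),
                center = center))
  }
  fit <- with_seed(seed, fa_em(X, k, max_iter, tol))
  c(fit, list(center = center))
}

# Hyvarinen's fixed-point ICA (symmetric decorrelation, logcosh contrast).
# Rows of X are observations; channel (column) means are removed here.
fastica_fixed_point <- function(X, k, max_iter = 200, tol = 1e-6) {
  X <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  sv <- svd(X, nu = k, nv = k)
  if (sum(sv$d > 1e-12) < k) abort("`k` exceeds the data rank.")
  # whitened scores: n x k with identity covariance
  Z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n)
  W <- matrix(rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*% t(e$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                       # n x k source estimates
    G <- tanh(WX)
    Gp <- 1 - G^2
    W_new <- crossprod(G, Z) / n - diag(colMeans(Gp), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  S_hat <- Z %*% t(W)                      # n x k sources
  # mixing in the original feature space: X ~ S_hat %*% A
  A <- solve(crossprod(S_hat), crossprod(S_hat, X))
  norms <- sqrt(rowSums(A^2))
  keep <- norms > 0
  A[keep, ] <- A[keep, , drop = FALSE] / norms[keep]
  S_hat[, keep] <- sweep(S_hat[, keep, drop = FALSE], 2, norms[keep], `*`)
  list(B = A, H = S_hat, error = frobenius_sq(X - S_hat %*% A))
}

# EM for the factor-analysis model x = Lambda z + noise, Psi diagonal.
fa_em <- function(X, k, max_iter = 200, tol = 1e-6) {
  n <- nrow(X)
  d <- ncol(X)
  cv <- pmax(colMeans(X^2), 1e-12)
  psi <- cv
  lambda <- matrix(rnorm(d * k, sd = sqrt(mean(cv)) / k), d, k)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    ipsi_l <- lambda / psi                       # d x k
    m_inv <- solve(diag(k) + crossprod(lambda, ipsi_l))
    beta <- m_inv %*% t(ipsi_l)                  # k x d posterior projection
    ez <- X %*% t(beta)                          # n x k
    szz <- n * m_inv + crossprod(ez)
    xez <- crossprod(X, ez)                      # d x k
    lambda <- xez %*% solve(szz)
    psi <- pmax(cv - rowSums(xez * lambda) / n, 1e-8 * mean(cv))
    # monitor convergence through the expected complete-data fit
    ll <- -sum(log(psi))
    if (abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) break
    ll_prev <- ll
  }
  B <- t(lambda)
  norms <- sqrt(rowSums(B^2))
  keep <- norms > 0
  B[keep, ] <- B[keep, , drop = FALSE] / norms[keep]
  ez[, keep] <- sweep(ez[, keep, drop = FALSE], 2, norms[keep], `*`)
  list(B = B, H = ez, error = frobenius_sq(X - ez %*% B))
}

#' Space-only decomposition into spatial modules
#'
#' Factorizes the `(S * T) x N` matricization so that neural activity is
#' described by `L` trial-invariant spatial modules (vectors over neurons)
#' with time- and trial-dependent activation coefficients
#' `h_k^s(t)` (model `r^s(t) = sum_k h_k^s(t) b_k + residual`).
#'
#' @inheritParams spatiotemporal_nmf
#' @param l number of spatial modules, `l <= N`.
#' @param method `"nmf"`, `"pca"`, `"ica"` or `"fa"`.
#' @param max_iter,tol,n_restarts iteration controls (NMF restarts only).
#' @return object of class `space_decomp` with `spatial_modules` (`L x N`)
#'   and `activations` (`S x T x L`).
#' @export
space_only_decomposition <- function(tensor, l,
                                     method = c("nmf", "pca", "ica", "fa"),
                                     max_iter = 500, tol = 1e-6,
                                     n_restarts = 5, seed = NULL) {
  method <- match.arg(method)
  l <- assert_scalar_count(l, "l")
  if (l > n_neurons(tensor)) abort("`l` exceeds the number of neurons.")
  R <- matricize_spatial(tensor)
  if (method == "nmf") {
    if (sum(R) == 0) abort("all-zero input: NMF updates are undefined.")
    seeds <- derive_seeds(seed, n_restarts)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- with_seed(seeds[[r]], nmf_mu(R, l, max_iter, tol))
      if (is.null(best) || fit$error < best$error) best <- fit
    }
    B <- best$B
    H <- best$H
    err <- best$error
    center <- NULL
  } else {
    fit <- linear_decomposition(R, l, method, seed, max_iter = max_iter, tol = tol)
    B <- fit$B
    H <- fit$H
    err <- fit$error
    center <- fit$center
  }
  acts <- aperm(array(H, dim = c(n_bins(tensor), n_trials(tensor), l)), c(2, 1, 3))
  structure(
    list(
      spatial_modules = B, activations = acts, method = method,
      reconstruction_error = err, center = center
    ),
    class = "space_decomp"
  )
}

#' @export
print.space_decomp <- function(x, ...) {
  cat(sprintf(
    "<space_decomp/%s> %d spatial modules x %d neurons, error %.4g\n",
    x$method, nrow(x$spatial_modules), ncol(x$spatial_modules),
    x$reconstruction_error
  ))
  invisible(x)
}

#' Infer activation coefficients for new trials under frozen modules
#'
#' For NMF decompositions the module matrix is frozen and only the
#' activations are iterated with multiplicative updates until tolerance;
#' for PCA/ICA/FA the new (centered) trials are projected onto the module
#' basis by least squares.
#'
#' @param decomp an `st_decomp`.
#' @param tensor new trials with matching `T` and `N`.
#' @param max_iter,tol iteration controls for the NMF route.
#' @param seed RNG seed for the NMF activation initialization.
#' @return `S_new x K` activation matrix.
#' @export
infer_activations <- function(decomp, tensor, max_iter = 500, tol = 1e-6,
                              seed = NULL) {
  stopifnot(inherits(decomp, "st_decomp"))
  d <- dim(decomp$modules[[1]])
  if (d[1] != n_bins(tensor) || d[2] != n_neurons(tensor)) {
    abort("tensor dimensions do not match the decomposition's modules.")
  }
  R <- matricize_spatiotemporal(tensor)
  B <- do.call(rbind, lapply(decomp$modules, module_to_row))
  if (decomp$method == "nmf") {
    fit <- with_seed(seed, {
      nmf_mu(R, nrow(B), max_iter, tol, B = B, update_b = FALSE)
    })
    fit$H
  } else {
    X <- sweep(R, 2, decomp$center)
    t(solve(tcrossprod(B), B %*% t(X)))
  }
}
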