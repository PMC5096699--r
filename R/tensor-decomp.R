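#' Space-by-time decomposition result
#'
#' Represents the Tucker-2 model `R^s = B^tem H^s B^spa + residual`:
#' `P` temporal modules (columns of `temporal_modules`, `T x P`), `L` spatial
#' modules (rows of `spatial_modules`, `L x N`) and a trial-dependent core
#' (`S x P x L`) whose slice `s` holds the activation coefficients
#' `h^s_{i,j}` combining temporal module `i` with spatial module `j`.
#'
#' @param temporal_modules `T x P` matrix.
#' @param spatial_modules `L x N` matrix.
#' @param core `S x P x L` array.
#' @param method `"nmf"` or `"tucker2"`.
#' @param reconstruction_error Frobenius objective at the returned solution.
#' @param iterations sweeps used by the winning run.
#' @return object of class `sbt_decomp`.
#' @keywords internal
new_sbt_decomp <- function(temporal_modules, spatial_modules, core, method,
                           reconstruction_error, iterations = NA_integer_) {
  structure(
    list(
      temporal_modules = temporal_modules, spatial_modules = spatial_modules,
      core = core, method = method,
      reconstruction_error = reconstruction_error, iterations = iterations
    ),
    class = "sbt_decomp"
  )
}

#' @export
print.sbt_decomp <- function(x, ...) {
  cat(sprintf(
    "<sbt_decomp/%s> %d temporal x %d spatial modules, %d trials, error %.4g\n",
    x$method, ncol(x$temporal_modules), nrow(x$spatial_modules),
    dim(x$core)[1], x$reconstruction_error
  ))
  invisible(x)
}

# --- internal unfoldings of the S x T x N count array ------------------------
# Rtall: (T*S) x N, trials stacked vertically (bin fastest within trial).
# Rwide: T x (N*S), trials stacked horizontally (neuron fastest within trial).
unfold_tall <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(2, 1, 3)), d[1] * d[2], d[3])
}
unfold_wide <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(2, 3, 1)), d[2], d[3] * d[1])
}

# core array (S,P,L) -> (P, L*S) with l fastest within s
core_flat <- function(H) {
  d <- dim(H)
  matrix(aperm(H, c(2, 3, 1)), d[2], d[3] * d[1])
}
# core array (S,P,L) -> (P*S) x L with p fastest within s
core_stack <- function(H) {
  d <- dim(H)
  matrix(aperm(H, c(2, 1, 3)), d[2] * d[1], d[3])
}
core_unstack <- function(M, s, p, l) {
  aperm(array(M, dim = c(p, s, l)), c(2, 1, 3))
}

# Reconstruction residual: sum_s || R^s - Btem H^s Bspa ||_F^2,
# computed on the tall unfolding.
sbt_objective <- function(Rtall, Btem, Bspa, H) {
  d <- dim(H)
  G <- Btem %*% core_flat(H)                              # T x (L*S)
  Gtall <- matrix(aperm(array(G, c(nrow(Btem), d[3], d[1])), c(1, 3, 2)),
                  nrow(Btem) * d[1], d[3])
  frobenius_sq(Rtall - Gtall %*% Bspa)
}

# One full multiplicative-update sweep (spatial, temporal, core).
sbt_sweep <- function(Rtall, Rwide, Btem, Bspa, H) {
  s <- dim(H)[1]; p <- dim(H)[2]; l <- dim(H)[3]
  tt <- nrow(Btem); nn <- ncol(Bspa)
  # spatial update: G^s = Btem H^s, stacked tall
  G <- Btem %*% core_flat(H)
  Gtall <- matrix(aperm(array(G, c(tt, l, s)), c(1, 3, 2)), tt * s, l)
  Bspa <- Bspa * crossprod(Gtall, Rtall) / (crossprod(Gtall) %*% Bspa + .mu_eps)
  # temporal update: V^s = H^s Bspa, stacked wide
  Vs <- core_stack(H) %*% Bspa                            # (P*S) x N
  Vwide <- matrix(aperm(array(Vs, c(p, s, nn)), c(1, 3, 2)), p, nn * s)
  Btem <- Btem * (Rwide %*% t(Vwide)) / (Btem %*% tcrossprod(Vwide) + .mu_eps)
  # core update, all trials at once
  X <- crossprod(Btem, Rwide)                             # P x (N*S)
  Xs <- matrix(aperm(array(X, c(p, nn, s)), c(1, 3, 2)), p * s, nn)
  num <- core_unstack(Xs %*% t(Bspa), s, p, l)
  AH <- core_unstack(
    core_stack(aperm(array(crossprod(Btem) %*% core_flat(H), c(p, l, s)),
                     c(3, 1, 2))) %*% tcrossprod(Bspa),
    s, p, l
  )
  H <- H * num / (AH + .mu_eps)
  list(Btem = Btem, Bspa = Bspa, H = H)
}

sbt_run <- function(A, p, l, max_iter, tol, H_only = FALSE,
                    Btem = NULL, Bspa = NULL) {
  d <- dim(A)
  Rtall <- unfold_tall(A)
  Rwide <- unfold_wide(A)
  if (is.null(Btem)) Btem <- matrix(runif(d[2] * p), d[2], p)
  if (is.null(Bspa)) Bspa <- matrix(runif(l * d[3]), l, d[3])
  H <- array(runif(d[1] * p * l), dim = c(d[1], p, l))
  prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (H_only) {
      s <- d[1]
      X <- crossprod(Btem, Rwide)
      Xs <- matrix(aperm(array(X, c(p, d[3], s)), c(1, 3, 2)), p * s, d[3])
      num <- core_unstack(Xs %*% t(Bspa), s, p, l)
      AH <- core_unstack(
        core_stack(aperm(array(crossprod(Btem) %*% core_flat(H), c(p, l, s)),
                         c(3, 1, 2))) %*% tcrossprod(Bspa),
        s, p, l
      )
      H <- H * num / (AH + .mu_eps)
    } else {
      upd <- sbt_sweep(Rtall, Rwide, Btem, Bspa, H)
      Btem <- upd$Btem; Bspa <- upd$Bspa; H <- upd$H
    }
    err <- sbt_objective(Rtall, Btem, Bspa, H)
    trace <- c(trace, err)
    if (is.finite(prev) && (prev - err) < tol * max(prev, .mu_eps)) break
    prev <- err
  }
  list(Btem = Btem, Bspa = Bspa, H = H, error = err, trace = trace,
       iterations = it)
}

#' Space-by-time NMF (non-negative Tucker-2)
#'
#' Decomposes a trial tensor into `P` non-negative temporal modules, `L`
#' non-negative spatial modules and a non-negative trial-dependent core by
#' alternating multiplicative updates of the spatial factor, the temporal
#' factor and the per-trial core slices, minimizing the Frobenius objective
#' `sum_s || R^s - B^tem H^s B^spa ||^2`. All three factors are initialized
#' with uniform(0, 1) entries; the objective is non-increasing across sweeps,
#' and the best of `n_restarts` runs is returned. At convergence every
#' temporal module (column) and spatial module (row) is scaled to unit norm
#' with the scales absorbed into the core, leaving the error unchanged.
#'
#' @param tensor a [trial_tensor()].
#' @param p number of temporal modules, `1 <= p <= T`.
#' @param l number of spatial modules, `1 <= l <= N`.
#' @param max_iter,tol stop when the relative objective decrease per sweep
#'   drops below `tol` or after `max_iter` sweeps.
#' @param n_restarts random restarts (lowest final objective wins).
#' @param seed RNG seed.
#' @return an `sbt_decomp` with `method = "nmf"`; the objective trace of the
#'   winning run is attached as attribute `"trace"`.
#' @export
space_by_time_nmf <- function(tensor, p, l, max_iter = 500, tol = 1e-6,
                              n_restarts = 5, seed = NULL) {
  p <- assert_scalar_count(p, "p")
  l <- assert_scalar_count(l, "l")
  A <- tensor$counts
  if (sum(A) == 0) abort("all-zero input: NMF updates are undefined.")
  if (p > n_bins(tensor)) abort("`p` exceeds the number of time bins.")
  if (l > n_neurons(tensor)) abort("`l` exceeds the number of neurons.")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seeds[[r]], sbt_run(A, p, l, max_iter, tol))
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  out <- normalize_sbt(best$Btem, best$Bspa, best$H)
  res <- new_sbt_decomp(out$Btem, out$Bspa, out$H, "nmf", best$error,
                        iterations = best$iterations)
  attr(res, "trace") <- best$trace
  res
}

# Unit-norm temporal columns and spatial rows; scales absorbed into the core.
normalize_sbt <- function(Btem, Bspa, H) {
  ntem <- sqrt(colSums(Btem^2))
  nspa <- sqrt(rowSums(Bspa^2))
  ntem_safe <- ifelse(ntem > 0, ntem, 1)
  nspa_safe <- ifelse(nspa > 0, nspa, 1)
  Btem <- sweep(Btem, 2, ntem_safe, `/`)
  Bspa <- sweep(Bspa, 1, nspa_safe, `/`)
  p <- length(ntem)
  l <- length(nspa)
  for (s in seq_len(dim(H)[1])) {
    hs <- matrix(H[s, , ], p, l)
    H[s, , ] <- diag(ntem_safe, p) %*% hs %*% diag(nspa_safe, l)
  }
  list(Btem = Btem, Bspa = Bspa, H = H)
}

#' Orthogonal Tucker-2 decomposition
#'
#' Tucker-2 with orthonormal factors (a tensor generalization of PCA), fit by
#' higher-order orthogonal iteration: the temporal factor is the leading `P`
#' left singular vectors of the mode-1 unfolding of the data projected on the
#' current spatial factor, and vice versa; the core follows in closed form as
#' `H^s = (B^tem)' R^s (B^spa)'`. Initialization is the HOSVD (leading
#' singular vectors of the raw unfoldings); each factor column/row has its
#' largest-magnitude entry made positive.
#'
#' @inheritParams space_by_time_nmf
#' @param max_iter,tol alternation controls on the fitted sum of squares.
#' @return an `sbt_decomp` with `method = "tucker2"`; factors satisfy
#'   `(B^tem)' B^tem = I` and `B^spa (B^spa)' = I` to machine precision.
#' @export
orthogonal_tucker2 <- function(tensor, p, l, max_iter = 100, tol = 1e-8) {
  p <- assert_scalar_count(p, "p")
  l <- assert_scalar_count(l, "l")
  A <- tensor$counts
  d <- dim(A)
  Rtall <- unfold_tall(A)
  Rwide <- unfold_wide(A)
  mode2 <- t(Rtall)                              # N x (T*S)
  if (p > min(d[2], qr(Rwide)$rank)) abort("`p` exceeds the mode-1 rank.")
  if (l > min(d[3], qr(mode2)$rank)) abort("`l` exceeds the mode-2 rank.")
  Btem <- svd(Rwide, nu = p)$u[, seq_len(p), drop = FALSE]
  Bspa <- t(svd(mode2, nu = l)$u[, seq_len(l), drop = FALSE])
  total <- frobenius_sq(A)
  fit_prev <- -Inf
  for (it in seq_len(max_iter)) {
    # temporal step: left singular vectors of the projected mode-1 unfolding
    Z1 <- Rtall %*% t(Bspa)                      # (T*S) x L
    M1 <- matrix(array(Z1, c(d[2], d[1], l)), d[2], d[1] * l)
    Btem <- svd(M1, nu = p)$u[, seq_len(p), drop = FALSE]
    # spatial step
    X <- crossprod(Btem, Rwide)                  # P x (N*S)
    M2 <- matrix(aperm(array(X, c(p, d[3], d[1])), c(1, 3, 2)), p * d[1], d[3])
    Bspa <- t(svd(M2, nv = l)$v[, seq_len(l), drop = FALSE])
    fit <- frobenius_sq(M2 %*% t(Bspa))
    if (fit - fit_prev < tol * max(total, 1)) break
    fit_prev <- fit
  }
  # sign convention: largest-magnitude entry of each module positive
  for (j in seq_len(p)) {
    if (Btem[which.max(abs(Btem[, j])), j] < 0) Btem[, j] <- -Btem[, j]
  }
  for (j in seq_len(l)) {
    if (Bspa[j, which.max(abs(Bspa[j, ]))] < 0) Bspa[j, ] <- -Bspa[j, ]
  }
  H <- project_core(A, Btem, Bspa)
  new_sbt_decomp(Btem, Bspa, H, "tucker2", total - frobenius_sq(H),
                 iterations = it)
}

# Closed-form core for orthonormal factors: H^s = Btem' R^s Bspa'.
project_core <- function(A, Btem, Bspa) {
  d <- dim(A)
  p <- ncol(Btem); l <- nrow(Bspa)
  X <- crossprod(Btem, unfold_wide(A))           # P x (N*S)
  Xs <- matrix(aperm(array(X, c(p, d[3], d[1])), c(1, 3, 2)), p * d[1], d[3])
  core_unstack(Xs %*% t(Bspa), d[1], p, l)
}

#' Infer core coefficients for new trials under frozen factors
#'
#' Orthogonal variant: closed form `H^s = (B^tem)' R^s (B^spa)'`. NMF
#' variant: core-only multiplicative updates with both factor matrices
#' frozen, iterated to tolerance.
#'
#' @param decomp an `sbt_decomp`.
#' @param tensor new trials with matching `T` and `N`.
#' @param max_iter,tol iteration controls for the NMF route.
#' @param seed RNG seed for the NMF core initialization.
#' @return `S_new x P x L` core array.
#' @export
infer_core <- function(decomp, tensor, max_iter = 500, tol = 1e-6,
                       seed = NULL) {
  stopifnot(inherits(decomp, "sbt_decomp"))
  if (nrow(decomp$temporal_modules) != n_bins(tensor) ||
      ncol(decomp$spatial_modules) != n_neurons(tensor)) {
    abort("tensor dimensions do not match the decomposition's factors.")
  }
  if (decomp$method == "tucker2") {
    return(project_core(tensor$counts, decomp$temporal_modules,
                        decomp$spatial_modules))
  }
  fit <- with_seed(seed, {
    sbt_run(tensor$counts, ncol(decomp$temporal_modules),
            nrow(decomp$spatial_modules), max_iter, tol, H_only = TRUE,
            Btem = decomp$temporal_modules, Bspa = decomp$spatial_modules)
  })
  fit$H
}

#' Frobenius reconstruction error of a decomposition on given data
#'
#' `sum_s || R^s - reconstruction^s ||_F^2`, the exact objective the
#' non-negative fits minimize.
#'
#' @param decomp an `sbt_decomp` or `st_decomp`.
#' @param tensor a [trial_tensor()] with matching dimensions.
#' @param core,activations optional coefficients for the trials in `tensor`
#'   (defaults to the fitted ones, requiring matching trial count).
#' @return scalar error.
#' @export
reconstruction_error <- function(decomp, tensor, core = NULL,
                                 activations = NULL) {
  if (inherits(decomp, "sbt_decomp")) {
    H <- core %||% decomp$core
    if (dim(H)[1] != n_trials(tensor)) {
      abort("core slices do not match the number of trials.")
    }
    return(sbt_objective(unfold_tall(tensor$counts), decomp$temporal_modules,
                         decomp$spatial_modules, H))
  }
  if (inherits(decomp, "st_decomp")) {
    H <- activations %||% decomp$activations
    R <- matricize_spatiotemporal(tensor)
    if (!is.null(decomp$center)) R <- sweep(R, 2, decomp$center)
    B <- do.call(rbind, lapply(decomp$modules, module_to_row))
    return(frobenius_sq(R - H %*% B))
  }
  abort("`decomp` must be an sbt_decomp or st_decomp.")
}
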