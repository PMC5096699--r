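# Small deterministic fixtures shared across tests.

tiny_tensor <- function(s = 4, t = 3, n = 2, seed = 1, labels = NULL) {
  set.seed(seed)
  counts <- array(rpois(s * t * n, 1.5), dim = c(s, t, n))
  trial_tensor(counts, bin_width = 10, window = c(0, t * 10),
               labels = labels %||% rep(c("a", "b"), length.out = s))
}

# Noiseless rank-structured tensor built from known factors.
factor_tensor <- function(s = 6, t = 5, n = 4, p = 1, l = 1, seed = 2) {
  set.seed(seed)
  btem <- matrix(runif(t * p), t, p)
  bspa <- matrix(runif(l * n), l, n)
  h <- array(runif(s * p * l, 0.5, 2), dim = c(s, p, l))
  counts <- array(0, dim = c(s, t, n))
  for (i in seq_len(s)) {
    counts[i, , ] <- btem %*% matrix(h[i, , ], p, l) %*% bspa
  }
  list(
    tensor = trial_tensor(counts, 10, c(0, t * 10), rep("x", s)),
    btem = btem, bspa = bspa, h = h
  )
}

gaussian_clusters <- function(n_per = 30, d = 3, sep = 6, seed = 3) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * d), n_per, d),
    matrix(rnorm(n_per * d, mean = sep), n_per, d)
  )
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}

`%||%` <- rlang::`%||%`

# Cheap deterministic checksum for leakage tests.
digest_counts <- function(x) {
  v <- as.vector(x)
  c(sum(v), sum(v * seq_along(v)), sum(v^2))
}
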