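#' Geodesic similarity between two modules
#'
#' Measures how close two module vectors point in the same direction on the
#' unit sphere: `sim(u, v) = 1 - (2 / pi) * arccos(<u, v> / (|u| |v|))`.
#' The value is 1 for identical directions, 0 for orthogonal vectors, and is
#' invariant to positive rescaling of either argument. For modules from
#' sign-indeterminate decompositions (PCA, ICA, FA, orthogonal Tucker-2) set
#' `signed = TRUE` to compare up to sign (the larger of `sim(u, v)` and
#' `sim(u, -v)` is returned).
#'
#' @param u,v numeric vectors or matrices (matrices are flattened); neither
#'   may be all-zero.
#' @param signed compare up to a global sign flip of `v`?
#' @return similarity in `[0, 1]` (signed variant in `[0, 1]` as well; values
#'   below 0.5 indicate angles beyond 45 degrees).
#' @export
#' @examples
#' geodesic_similarity(c(1, 0), c(1, 1)) # 0.5: a 45-degree angle
geodesic_similarity <- function(u, v, signed = FALSE) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) abort("`u` and `v` must have equal length.")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("geodesic similarity is undefined for a zero vector.")
  ct <- sum(u * v) / (nu * nv)
  if (signed) ct <- abs(ct)
  ct <- min(1, max(-1, ct))
  1 - (2 / pi) * acos(ct)
}

# Pairwise similarity matrix between two lists of modules.
similarity_matrix <- function(found, truth, signed = FALSE) {
  outer(
    seq_along(found), seq_along(truth),
    Vectorize(function(i, j) geodesic_similarity(found[[i]], truth[[j]], signed = signed))
  )
}

# Optimal one-to-one assignment maximizing total similarity.
# Exhaustive enumeration for small sets; LSAP (Hungarian) otherwise.
# Ties broken toward the lexicographically smallest assignment.
best_assignment <- function(sim, exhaustive_limit = 6L) {
  n <- nrow(sim)
  if (n <= exhaustive_limit) {
    perms <- permutations(n)
    totals <- vapply(seq_len(nrow(perms)), function(i) {
      sum(sim[cbind(seq_len(n), perms[i, ])])
    }, numeric(1))
    best <- which(totals >= max(totals) - 1e-12)
    # permutations() emits rows in lexicographic order; the first tie wins.
    perms[best[1], ]
  } else {
    as.integer(clue::solve_LSAP(sim, maximum = TRUE))
  }
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Match two module sets and compute module recovery similarity
#'
#' Finds the one-to-one assignment between `found` and `truth` modules that
#' maximizes total pairwise geodesic similarity (exhaustive enumeration for
#' up to 6 modules, Hungarian assignment beyond) and reports each matched
#' pair. Space-by-time decompositions are expanded to their `P * L`
#' outer-product modules before matching, so they can be compared against
#' spatiotemporal ground-truth patterns.
#'
#' @param found,truth module sets: a list of numeric vectors/matrices, a
#'   decomposition object (`st_decomp`, `sbt_decomp`), or a `rate_patterns`
#'   object.
#' @param signed compare up to sign (use for PCA/ICA/FA/orthogonal Tucker-2).
#' @return tibble with columns `found`, `truth`, `similarity` (one row per
#'   matched pair).
#' @export
match_modules <- function(found, truth, signed = FALSE) {
  found <- as_module_list(found)
  truth <- as_module_list(truth)
  if (length(found) == 0 || length(truth) == 0) {
    abort("both module sets must be non-empty.")
  }
  if (length(found) != length(truth)) {
    abort(sprintf(
      "module counts differ after expansion: %d found vs %d truth.",
      length(found), length(truth)
    ))
  }
  sim <- similarity_matrix(found, truth, signed = signed)
  assign <- best_assignment(sim)
  tibble::tibble(
    found = seq_along(found),
    truth = assign,
    similarity = sim[cbind(seq_along(found), assign)]
  )
}

#' Module recovery similarity between two module sets
#'
#' The matched-pair mean geodesic similarity between recovered and
#' ground-truth modules, in percent. 100% means every recovered module points
#' exactly along a distinct ground-truth module.
#'
#' @inheritParams match_modules
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' a <- list(c(1, 0), c(0, 1))
#' module_set_similarity(a, rev(a)) # 100: matching is order-invariant
module_set_similarity <- function(found, truth, signed = FALSE) {
  100 * mean(match_modules(found, truth, signed = signed)$similarity)
}

# Coerce decomposition objects / pattern sets to a plain list of modules.
as_module_list <- function(x) {
  if (inherits(x, "sbt_decomp")) return(expand_sbt_modules(x))
  if (inherits(x, "st_decomp")) return(x$modules)
  if (inherits(x, "rate_patterns")) return(x$patterns)
  if (is.list(x)) return(x)
  abort("cannot interpret object as a module set.")
}

#' Expand a space-by-time decomposition to outer-product modules
#'
#' Each pair (temporal module `i`, spatial module `j`) yields the `T x N`
#' rank-one module `b_i^tem (b_j^spa)^T`, giving `P * L` spatiotemporal
#' modules comparable to matrix-decomposition modules.
#'
#' @param decomp an `sbt_decomp`.
#' @return list of `P * L` matrices `T x N`, ordered spatial-fastest.
#' @export
expand_sbt_modules <- function(decomp) {
  p <- ncol(decomp$temporal_modules)
  l <- nrow(decomp$spatial_modules)
  out <- vector("list", p * l)
  idx <- 1L
  for (i in seq_len(p)) {
    for (j in seq_len(l)) {
      out[[idx]] <- outer(decomp$temporal_modules[, i], decomp$spatial_modules[j, ])
      idx <- idx + 1L
    }
  }
  out
}
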