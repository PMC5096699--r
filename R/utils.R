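#' @importFrom rlang abort %||%
#' @importFrom stats rpois runif rnorm sd var cor predict
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards. `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seeds for nested stochastic steps, kept below 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  as.list((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

frobenius_sq <- function(x) sum(x * x)

# Machine-epsilon floor used in multiplicative-update denominators.
.mu_eps <- .Machine$double.eps
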