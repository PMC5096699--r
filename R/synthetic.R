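#' Ground-truth firing-rate pattern set
#'
#' Holds `K` firing-rate maps (each `T x N`, in Hz) plus the background rate
#' against which they are embedded. Patterns are the simulator's input and the
#' reference for module-recovery evaluation.
#'
#' @param patterns list of `T x N` matrices of foreground rates in Hz (zero
#'   outside the pattern support).
#' @param background_rate background firing rate in Hz.
#' @param bin_width bin width in ms.
#' @param conditions optional named list mapping stimulus labels to integer
#'   vectors of pattern indices (a fixed-conditions design table).
#' @param info_axis optional character tag per pattern (`"space_time"`,
#'   `"space"`, `"time"`) used by the information-analysis presets.
#' @return object of class `rate_patterns`.
#' @export
rate_patterns <- function(patterns, background_rate, bin_width = 10,
                          conditions = NULL, info_axis = NULL) {
  stopifnot(is.list(patterns), length(patterns) >= 1)
  dims <- unique(lapply(patterns, dim))
  if (length(dims) != 1) abort("all patterns must share dimensions T x N.")
  if (any(vapply(patterns, function(p) any(p < 0), logical(1)))) {
    abort("rates must be non-negative.")
  }
  fg <- unlist(lapply(patterns, function(p) p[p > 0]))
  if (length(fg) > 0 && any(fg < background_rate)) {
    abort("foreground rates must be >= background rate.")
  }
  structure(
    list(
      patterns = patterns,
      background_rate = background_rate,
      bin_width = bin_width,
      conditions = conditions,
      info_axis = info_axis
    ),
    class = "rate_patterns"
  )
}

#' @export
print.rate_patterns <- function(x, ...) {
  d <- dim(x$patterns[[1]])
  cat(sprintf(
    "<rate_patterns> %d patterns, %d bins x %d neurons, background %g Hz\n",
    length(x$patterns), d[1], d[2], x$background_rate
  ))
  if (!is.null(x$conditions)) {
    cat(sprintf("  %d stimulus conditions\n", length(x$conditions)))
  }
  invisible(x)
}

#' Canonical block geometry for the simulation presets
#'
#' The figures' geometry in the source experiments is qualitative; this
#' package fixes one canonical realization: 20 neurons, 30 bins of 10 ms
#' (a 0-300 ms window), rectangular blocks of 6 neurons by 8 bins built as
#' the combinations of 2 spatial neuron groups and 2 temporal windows.
#'
#' @param n_neurons,n_bins population and window size.
#' @param bin_width bin width, ms.
#' @param block_neurons,block_bins block extent.
#' @param neuron_start,bin_start 1-based position of the first group/window.
#' @return list of geometry parameters.
#' @export
block_geometry <- function(n_neurons = 20, n_bins = 30, bin_width = 10,
                           block_neurons = 6, block_bins = 8,
                           neuron_start = 3, bin_start = 5) {
  list(
    n_neurons = n_neurons, n_bins = n_bins, bin_width = bin_width,
    block_neurons = block_neurons, block_bins = block_bins,
    neuron_start = neuron_start, bin_start = bin_start
  )
}

# One rectangular block pattern: `fg` Hz on rows `bins` x cols `neurons`.
block_pattern <- function(geom, neurons, bins, fg) {
  if (max(neurons) > geom$n_neurons || max(bins) > geom$n_bins ||
      min(neurons) < 1 || min(bins) < 1) {
    abort("block exceeds the (bins x neurons) bounds of the geometry.")
  }
  p <- matrix(0, geom$n_bins, geom$n_neurons)
  p[bins, neurons] <- fg
  p
}

# Neuron-group / time-window overlap (in cells) per overlap level 0..3.
# Calibrated (closed form, a priori) so the mean pairwise geodesic overlap
# of the four blocks spans roughly 9.8% (level 0) to 32.2% (level 3).
overlap_level_sharing <- function(level) {
  switch(as.character(level),
    "0" = c(n = 1L, t = 2L),
    "1" = c(n = 2L, t = 2L),
    "2" = c(n = 1L, t = 4L),
    "3" = c(n = 3L, t = 5L),
    abort("`level` must be 0, 1, 2 or 3.")
  )
}

# The four group-x-window combination blocks for given sharing.
combo_blocks <- function(geom, share_n, share_t, fg) {
  g1 <- seq(geom$neuron_start, length.out = geom$block_neurons)
  g2 <- g1 + geom$block_neurons - share_n
  w1 <- seq(geom$bin_start, length.out = geom$block_bins)
  w2 <- w1 + geom$block_bins - share_t
  lapply(
    list(list(g1, w1), list(g1, w2), list(g2, w1), list(g2, w2)),
    function(gw) block_pattern(geom, gw[[1]], gw[[2]], fg)
  )
}

#' Build ground-truth block firing patterns
#'
#' Generates the rate-pattern presets used in the validation simulations:
#'
#' * `"separable"`: four partly overlapping blocks formed as the combinations
#'   of 2 neuron groups x 2 time windows (adjacent groups share 2 neurons,
#'   adjacent windows 2 bins). Each block is an outer product of a neuron
#'   indicator and a bin indicator, so the set is exactly representable by 2
#'   spatial and 2 temporal modules.
#' * `"sequential"`: four non-separable patterns; each block's 6 neurons are
#'   split into 3 pairs activating in successive 8-bin steps (a staircase).
#' * `"overlap"`: the separable combination blocks with group/window sharing
#'   increasing with `level` 0-3; block area is constant and the mean
#'   pairwise overlap increases strictly with level, spanning roughly
#'   9.8%-32.2%. Includes a 6-condition design table: every unordered pair
#'   of the 4 blocks is one stimulus.
#' * `"mixture"`: four disjoint base blocks plus one of four mixing tables
#'   (`mixture_set` 1-4) composing observable patterns as sums of bases.
#' * `"info_type"`: three pattern types x two variants; the variants of the
#'   `"space"` type differ only in which neurons fire, of the `"time"` type
#'   only in when they fire, and of the `"space_time"` type in both. One
#'   stimulus condition per variant.
#'
#' @param preset preset name, see above.
#' @param fg_rate foreground rate in Hz (default 300, the high-SNR case).
#' @param bg_rate background rate in Hz (default 2).
#' @param level overlap level 0-3 (for `preset = "overlap"`).
#' @param mixture_set mixing table 1-4 (for `preset = "mixture"`).
#' @param geometry a [block_geometry()].
#' @return a [rate_patterns()] object.
#' @export
#' @examples
#' pats <- make_block_patterns("separable")
#' pattern_snr(pats) # 150 for every block: 300 Hz over a 2 Hz background
make_block_patterns <- function(preset = c("separable", "sequential", "overlap",
                                           "mixture", "info_type"),
                                fg_rate = 300, bg_rate = 2, level = 0,
                                mixture_set = 1,
                                geometry = block_geometry()) {
  preset <- match.arg(preset)
  geom <- geometry
  if (preset == "separable") {
    pats <- combo_blocks(geom, 2L, 2L, fg_rate)
    return(rate_patterns(pats, bg_rate, geom$bin_width))
  }
  if (preset == "overlap") {
    sh <- overlap_level_sharing(level)
    pats <- combo_blocks(geom, sh[["n"]], sh[["t"]], fg_rate)
    pairs <- utils::combn(4, 2, simplify = FALSE)
    conditions <- stats::setNames(
      pairs, vapply(pairs, function(p) paste0("s", p[1], p[2]), character(1))
    )
    return(rate_patterns(pats, bg_rate, geom$bin_width, conditions = conditions))
  }
  if (preset == "sequential") {
    # same anchors as the separable blocks; each block's 6 neurons split into
    # 3 pairs activating at successive 6-bin steps (a non-separable staircase)
    g1 <- seq(geom$neuron_start, length.out = geom$block_neurons)
    g2 <- g1 + geom$block_neurons - 2L
    anchors <- c(geom$bin_start, geom$bin_start + geom$block_bins - 2L)
    step <- geom$block_bins - 2L
    pats <- list()
    for (g in list(g1, g2)) {
      for (a in anchors) {
        p <- matrix(0, geom$n_bins, geom$n_neurons)
        for (m in 1:3) {
          nb <- g[(2 * m - 1):(2 * m)]
          tb <- seq(a + (m - 1) * step, length.out = geom$block_bins)
          if (max(tb) > geom$n_bins) {
            abort("sequential staircase exceeds the time window.")
          }
          p[tb, nb] <- fg_rate
        }
        pats[[length(pats) + 1L]] <- p
      }
    }
    return(rate_patterns(pats, bg_rate, geom$bin_width))
  }
  if (preset == "mixture") {
    if (!mixture_set %in% 1:4) abort("`mixture_set` must be in 1..4.")
    base_n <- split(seq_len(geom$n_neurons), rep(1:4, each = geom$n_neurons / 4))
    starts <- round(seq(1, geom$n_bins - geom$block_bins + 1, length.out = 4))
    bases <- lapply(1:4, function(k) {
      block_pattern(
        geom, base_n[[k]],
        seq(starts[k], length.out = geom$block_bins), fg_rate
      )
    })
    mix <- switch(mixture_set,
      diag(4),
      outer(1:4, 1:4, function(i, j) as.numeric(j <= i)),       # cumulative
      rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1), c(1, 0, 0, 1)),
      1 - diag(4)                                               # complements
    )
    obs <- lapply(1:4, function(i) {
      Reduce(`+`, Map(`*`, bases, mix[i, ]))
    })
    out <- rate_patterns(obs, bg_rate, geom$bin_width)
    attr(out, "bases") <- bases
    attr(out, "mixing") <- mix
    return(out)
  }
  # info_type: three pattern types x two variants, constant area (48 cells)
  v <- list(
    space_time_a = list(n = 1:6,   t = 3:10),
    space_time_b = list(n = 13:18, t = 19:26),
    space_a      = list(n = 1:6,   t = 12:19),
    space_b      = list(n = 13:18, t = 12:19),
    time_a       = list(n = 8:13,  t = 2:9),
    time_b       = list(n = 8:13,  t = 20:27)
  )
  pats <- lapply(v, function(b) block_pattern(geom, b$n, b$t, fg_rate))
  conditions <- stats::setNames(as.list(seq_along(v)), names(v))
  rate_patterns(
    unname(pats), bg_rate, geom$bin_width, conditions = conditions,
    info_axis = rep(c("space_time", "space", "time"), each = 2)
  )
}

#' Signal-to-noise ratio of each pattern
#'
#' SNR of a pattern is the ratio between its (maximal) foreground firing rate
#' and the background firing rate.
#'
#' @param patterns a [rate_patterns()] object.
#' @return numeric vector, one SNR per pattern.
#' @export
pattern_snr <- function(patterns) {
  if (patterns$background_rate <= 0) {
    abort("SNR is undefined for a zero background rate.")
  }
  vapply(patterns$patterns, max, numeric(1)) / patterns$background_rate
}

#' Mean pairwise overlap of a pattern set
#'
#' The geodesic similarity averaged over all unordered distinct pattern
#' pairs, in percent. Identical patterns overlap 100%; disjoint-support
#' patterns overlap 0%.
#'
#' @param patterns a [rate_patterns()] object with at least two patterns.
#' @return percentage in `[0, 100]`.
#' @export
pattern_overlap <- function(patterns) {
  k <- length(patterns$patterns)
  if (k < 2) abort("overlap needs at least two patterns.")
  pairs <- utils::combn(k, 2)
  sims <- apply(pairs, 2, function(ij) {
    geodesic_similarity(patterns$patterns[[ij[1]]], patterns$patterns[[ij[2]]])
  })
  100 * mean(sims)
}

#' Trial presence design for the simulator
#'
#' @param mode `"independent_mixture"`: each pattern is independently present
#'   in a trial with probability `presence_probability`; the stimulus label
#'   records the presence combination. `"fixed_conditions"`: each stimulus
#'   activates a fixed subset of patterns given by `conditions` (defaulting
#'   to the pattern set's own design table).
#' @param presence_probability per-pattern presence probability (mixture mode).
#' @param conditions named list stimulus -> integer vector of pattern indices.
#' @return object of class `presence_design`.
#' @export
presence_design <- function(mode = c("independent_mixture", "fixed_conditions"),
                            presence_probability = 0.5, conditions = NULL) {
  mode <- match.arg(mode)
  if (presence_probability < 0 || presence_probability > 1) {
    abort("`presence_probability` must be in [0, 1].")
  }
  if (mode == "fixed_conditions" && !is.null(conditions)) {
    if (any(vapply(conditions, length, integer(1)) == 0)) {
      abort("condition subsets must be non-empty.")
    }
  }
  structure(
    list(mode = mode, presence_probability = presence_probability,
         conditions = conditions),
    class = "presence_design"
  )
}

#' Generate Poisson spike-count trials from ground-truth patterns
#'
#' For each trial the firing-rate map is the background rate plus the sum of
#' the active patterns' foreground rates (the additive superposition under
#' which the patterns are exactly the non-negative parts of the data, as the
#' linear decomposition models assume). `superposition = "max"` instead
#' replaces the background by the element-wise maximum of the active
#' foreground rates, keeping the SNR constant in overlap regions. Each bin
#' count is drawn as Poisson(rate x bin width).
#'
#' @param patterns a [rate_patterns()] object.
#' @param design a [presence_design()]; defaults to the independent 50%
#'   mixture used in the module-recovery simulations, or to the pattern set's
#'   condition table when one is attached.
#' @param n_trials number of trials: total trials in mixture mode, trials per
#'   stimulus in fixed-conditions mode.
#' @param seed RNG seed; a fixed seed yields a bit-identical tensor.
#' @param superposition `"add"` (default) or `"max"` rule for co-active
#'   overlapping patterns.
#' @return a [trial_tensor()]. Attribute `"presence"` records the S x K
#'   pattern-presence indicator matrix.
#' @export
generate_trials <- function(patterns, design = NULL, n_trials, seed = NULL,
                            superposition = c("add", "max")) {
  superposition <- match.arg(superposition)
  n_trials <- assert_scalar_count(n_trials, "n_trials")
  if (is.null(design)) {
    design <- if (!is.null(patterns$conditions)) {
      presence_design("fixed_conditions", conditions = patterns$conditions)
    } else {
      presence_design("independent_mixture", presence_probability = 0.5)
    }
  }
  k <- length(patterns$patterns)
  d <- dim(patterns$patterns[[1]])
  with_seed(seed, {
    if (design$mode == "independent_mixture") {
      pres <- matrix(
        runif(n_trials * k) < design$presence_probability,
        nrow = n_trials, ncol = k
      )
      labels <- apply(pres, 1, function(z) paste0("m", paste(as.integer(z), collapse = "")))
      s_total <- n_trials
    } else {
      conditions <- design$conditions %||% patterns$conditions
      if (is.null(conditions)) {
        abort("fixed-conditions design requires a condition table.")
      }
      if (max(unlist(conditions)) > k) {
        abort("condition table refers to a pattern index beyond the set.")
      }
      s_total <- n_trials * length(conditions)
      pres <- matrix(FALSE, s_total, k)
      labels <- character(s_total)
      row <- 1L
      for (ci in seq_along(conditions)) {
        for (r in seq_len(n_trials)) {
          pres[row, conditions[[ci]]] <- TRUE
          labels[row] <- names(conditions)[ci]
          row <- row + 1L
        }
      }
    }
    bg <- patterns$background_rate
    dt_s <- patterns$bin_width / 1000
    counts <- array(0L, dim = c(s_total, d[1], d[2]))
    for (s in seq_len(s_total)) {
      active <- which(pres[s, ])
      rate <- matrix(bg, d[1], d[2])
      if (length(active) > 0) {
        if (superposition == "max") {
          for (a in active) rate <- pmax(rate, patterns$patterns[[a]])
        } else {
          rate <- rate + Reduce(`+`, patterns$patterns[active])
        }
      }
      counts[s, , ] <- rpois(d[1] * d[2], as.vector(rate) * dt_s)
    }
    out <- trial_tensor(
      counts, patterns$bin_width,
      window = c(0, d[1] * patterns$bin_width), labels = labels
    )
    attr(out, "presence") <- pres
    out
  })
}
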