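#' Destroy temporal structure: permute time bins within trials
#'
#' Applies a random permutation of the time-bin indices to each trial,
#' jointly across neurons by default (`scope = "joint"`), so that all
#' information carried by response timing is destroyed while per-neuron
#' per-trial spike counts are exactly conserved. `scope = "per_neuron"`
#' draws an independent permutation for every neuron.
#'
#' @param tensor a [trial_tensor()].
#' @param scope `"joint"` or `"per_neuron"`.
#' @param seed RNG seed.
#' @return a shuffled [trial_tensor()].
#' @export
shuffle_time <- function(tensor, scope = c("joint", "per_neuron"), seed = NULL) {
  scope <- match.arg(scope)
  d <- dim(tensor$counts)
  with_seed(seed, {
    counts <- tensor$counts
    for (s in seq_len(d[1])) {
      if (scope == "joint") {
        counts[s, , ] <- counts[s, sample.int(d[2]), ]
      } else {
        for (n in seq_len(d[3])) {
          counts[s, , n] <- counts[s, sample.int(d[2]), n]
        }
      }
    }
    trial_tensor(counts, tensor$bin_width, tensor$window, tensor$labels)
  })
}

#' Destroy spatial structure: permute neuron identities within trials
#'
#' Applies a random permutation of the neuron indices to each trial (jointly
#' across time bins by default), destroying neuron-identity information while
#' conserving the per-bin pooled population count exactly.
#'
#' @param tensor a [trial_tensor()].
#' @param scope `"joint"` or `"per_bin"`.
#' @param seed RNG seed.
#' @return a shuffled [trial_tensor()].
#' @export
shuffle_space <- function(tensor, scope = c("joint", "per_bin"), seed = NULL) {
  scope <- match.arg(scope)
  d <- dim(tensor$counts)
  with_seed(seed, {
    counts <- tensor$counts
    for (s in seq_len(d[1])) {
      if (scope == "joint") {
        counts[s, , ] <- counts[s, , sample.int(d[3])]
      } else {
        for (t in seq_len(d[2])) {
          counts[s, t, ] <- counts[s, t, sample.int(d[3])]
        }
      }
    }
    trial_tensor(counts, tensor$bin_width, tensor$window, tensor$labels)
  })
}

#' Keep only each neuron's first spike per trial
#'
#' Reduces a spike-event table to the latency code: for every (trial, neuron)
#' pair only the earliest spike survives. Silent neurons stay silent; the
#' operation is idempotent.
#'
#' @param events spike-event data frame (see [bin_spikes()]).
#' @return filtered event data frame.
#' @export
first_spike_filter <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) return(events)
  events |>
    dplyr::group_by(.data$trial, .data$neuron) |>
    dplyr::slice_min(.data$time_ms, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Reduce effective temporal precision by within-group bin shuffling
#'
#' Splits the time axis into consecutive groups of `k` bins and randomly
#' permutes the bin order within each group, independently for every neuron
#' and trial by default. Spike counts per (trial, neuron, group) are exactly
#' conserved, so only timing at a resolution finer than `k * bin_width` ms is
#' destroyed. With `k = 1` the data are untouched; with `k = T` the shuffle
#' is a full within-trial time shuffle. If `k` does not divide `T`, the
#' trailing `T mod k` bins form a shorter final group.
#'
#' @param tensor a [trial_tensor()].
#' @param k bins per shuffle group (>= 1).
#' @param scope `"per_neuron"` (default) or `"joint"` across neurons.
#' @param seed RNG seed.
#' @return a [trial_tensor()] at coarsened effective precision.
#' @export
coarsen_precision <- function(tensor, k, scope = c("per_neuron", "joint"),
                              seed = NULL) {
  scope <- match.arg(scope)
  k <- assert_scalar_count(k, "k")
  d <- dim(tensor$counts)
  if (k == 1) return(tensor)
  groups <- split(seq_len(d[2]), ceiling(seq_len(d[2]) / k))
  with_seed(seed, {
    counts <- tensor$counts
    for (s in seq_len(d[1])) {
      for (g in groups) {
        if (length(g) == 1) next
        if (scope == "joint") {
          counts[s, g, ] <- counts[s, g[sample.int(length(g))], ]
        } else {
          for (n in seq_len(d[3])) {
            counts[s, g, n] <- counts[s, g[sample.int(length(g))], n]
          }
        }
      }
    }
    trial_tensor(counts, tensor$bin_width, tensor$window, tensor$labels)
  })
}

#' Quantify space, time, latency and precision contributions to decoding
#'
#' Runs the decomposition-plus-LDA decoding pipeline under a set of data
#' transformations that selectively destroy components of the population
#' code, and reports the accuracy of each condition together with its drop
#' relative to the intact (`space_and_time`) condition:
#'
#' * `space_and_time`: intact data (total information).
#' * `space_only`: time bins shuffled within trials before module fitting, on
#'   training and test partitions alike; only rate and neuron identity remain.
#' * `time_only`: neuron identities shuffled within trials; only the pooled
#'   temporal profile remains.
#' * `latency`: spike trains reduced to each neuron's first spike (requires
#'   `events`).
#' * `precision(k)`: bins shuffled within groups of `k` (see
#'   [coarsen_precision()]); one condition per requested `k`.
#' * `population_fraction(f)`: decoding from random neuron subsets of
#'   fraction `f`, averaged over `n_subsets` draws.
#'
#' @param tensor a [trial_tensor()].
#' @param model,counts,n_train,opts as in [decode_pipeline()].
#' @param conditions character vector among `"space_and_time"`,
#'   `"space_only"`, `"time_only"`, `"latency"`, `"precision"`,
#'   `"population_fraction"`.
#' @param precision_k group sizes for the precision conditions.
#' @param fractions population fractions for the subsampling conditions.
#' @param n_subsets random subsets averaged per fraction.
#' @param events spike-event table (needed for the latency condition).
#' @param seed RNG seed.
#' @return tibble with columns `condition`, `accuracy`, `delta_vs_full`.
#' @export
space_time_report <- function(tensor, model, counts, n_train,
                              conditions = c("space_and_time", "space_only",
                                             "time_only"),
                              precision_k = c(2, 5, 10), fractions = 0.5,
                              n_subsets = 3, events = NULL, seed = NULL,
                              opts = list()) {
  allowed <- c("space_and_time", "space_only", "time_only", "latency",
               "precision", "population_fraction")
  bad <- setdiff(conditions, allowed)
  if (length(bad) > 0) abort(paste0("unknown conditions: ", paste(bad, collapse = ", ")))
  seeds <- derive_seeds(seed, 64)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[[si]]
  }
  run <- function(x, sd) {
    decode_pipeline(x, model, counts, n_train, seed = sd, opts = opts)$accuracy
  }
  rows <- list()
  base_seed <- next_seed()
  full_acc <- run(tensor, base_seed)
  add <- function(name, acc) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(condition = name, accuracy = acc)
  }
  if ("space_and_time" %in% conditions) add("space_and_time", full_acc)
  if ("space_only" %in% conditions) {
    add("space_only", run(shuffle_time(tensor, seed = next_seed()), base_seed))
  }
  if ("time_only" %in% conditions) {
    add("time_only", run(shuffle_space(tensor, seed = next_seed()), base_seed))
  }
  if ("latency" %in% conditions) {
    if (is.null(events)) abort("the latency condition requires `events`.")
    filtered <- first_spike_filter(events)
    lat_tensor <- bin_spikes(filtered, tensor$bin_width, tensor$window,
                             n_neurons = n_neurons(tensor))
    add("latency", run(lat_tensor, base_seed))
  }
  if ("precision" %in% conditions) {
    for (k in precision_k) {
      add(sprintf("precision(%d)", k),
          run(coarsen_precision(tensor, k, seed = next_seed()), base_seed))
    }
  }
  if ("population_fraction" %in% conditions) {
    for (f in fractions) {
      n_keep <- max(1L, round(f * n_neurons(tensor)))
      if (n_keep == n_neurons(tensor)) {
        add(sprintf("population_fraction(%g)", f), full_acc)
        next
      }
      accs <- vapply(seq_len(n_subsets), function(i) {
        sub <- with_seed(next_seed(), sample.int(n_neurons(tensor), n_keep))
        subset_tensor <- trial_tensor(
          tensor$counts[, , sub, drop = FALSE], tensor$bin_width,
          tensor$window, tensor$labels
        )
        run(subset_tensor, base_seed)
      }, numeric(1))
      add(sprintf("population_fraction(%g)", f), mean(accs))
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(delta_vs_full = full_acc - .data$accuracy)
}
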