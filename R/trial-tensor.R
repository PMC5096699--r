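#' Trial tensor of binned population spike counts
#'
#' A `trial_tensor` holds non-negative integer spike counts for `S` trials,
#' `T` post-stimulus time bins and `N` neurons, together with the bin width,
#' the analysis window and one stimulus label per trial. It is the object all
#' decompositions in this package consume: trial `s` corresponds to the
#' `T x N` count matrix `x$counts[s, , ]`.
#'
#' @param counts numeric array, trials x time-bins x neurons, non-negative
#'   integers.
#' @param bin_width bin width in ms.
#' @param window length-2 numeric, analysis window `(start_ms, end_ms)`;
#'   the window length must equal `T * bin_width`.
#' @param labels per-trial stimulus labels (factor or coercible); length `S`.
#'
#' @return An object of class `trial_tensor` with elements `counts`,
#'   `bin_width`, `window` and `labels`.
#' @export
trial_tensor <- function(counts, bin_width, window, labels) {
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    abort("`counts` must be a 3-way array (trials x bins x neurons).")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be finite and non-negative.")
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    abort("`window` must be (start_ms, end_ms) with start < end.")
  }
  n_bins <- dim(counts)[2]
  if (abs((window[2] - window[1]) / bin_width - n_bins) > 1e-8) {
    abort("window length must equal n_bins * bin_width.")
  }
  labels <- as.factor(labels)
  if (length(labels) != dim(counts)[1]) {
    abort("`labels` must have one entry per trial.")
  }
  structure(
    list(
      counts = counts,
      bin_width = as.numeric(bin_width),
      window = as.numeric(window),
      labels = labels
    ),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<trial_tensor> %d trials x %d bins x %d neurons (bin %g ms, window %g-%g ms)\n",
    d[1], d[2], d[3], x$bin_width, x$window[1], x$window[2]
  ))
  cat(sprintf(
    "  %d stimuli, %d spikes total\n",
    nlevels(x$labels), sum(x$counts)
  ))
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$counts)

n_trials <- function(x) dim(x$counts)[1]
n_bins <- function(x) dim(x$counts)[2]
n_neurons <- function(x) dim(x$counts)[3]

# Subset a trial_tensor by trial index, keeping metadata.
tensor_subset <- function(x, idx) {
  trial_tensor(
    x$counts[idx, , , drop = FALSE],
    x$bin_width, x$window, droplevels(x$labels[idx])
  )
}

#' Bin a spike-event table into a trial tensor
#'
#' Counts spikes per (trial, time-bin, neuron) over half-open bins
#' `[start + t * bin_width, start + (t + 1) * bin_width)`. A spike exactly at
#' the window end falls outside the window. Events outside the window are
#' dropped and their number reported via the `"dropped"` attribute and a
#' warning.
#'
#' @param events data frame with columns `trial`, `stimulus`, `neuron`,
#'   `time_ms`: trial index (>= 1 or any dense ids), stimulus label,
#'   0-based or 1-based dense neuron index, and spike time in ms relative to
#'   stimulus onset.
#' @param bin_width bin width in ms.
#' @param window length-2 numeric `(start_ms, end_ms)`; `bin_width` must
#'   divide the window length.
#' @param n_neurons total number of neurons; defaults to the largest neuron
#'   index present (indices must be dense `0..N-1` or `1..N`).
#'
#' @return A [trial_tensor()]. Attribute `"dropped"` carries the number of
#'   out-of-window events.
#' @export
#' @examples
#' ev <- tibble::tibble(trial = 1, stimulus = "a", neuron = 1, time_ms = 15)
#' bin_spikes(ev, bin_width = 10, window = c(0, 300))
bin_spikes <- function(events, bin_width, window, n_neurons = NULL) {
  stopifnot(is.data.frame(events))
  need <- c("trial", "stimulus", "neuron", "time_ms")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("`events` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (window[2] <= window[1]) abort("window start must be < end.")
  len <- window[2] - window[1]
  n_t <- len / bin_width
  if (abs(n_t - round(n_t)) > 1e-8) {
    abort("`bin_width` must divide the window length exactly.")
  }
  n_t <- as.integer(round(n_t))

  neuron <- as.integer(events$neuron)
  zero_based <- length(neuron) > 0 && min(neuron) == 0L
  if (zero_based) neuron <- neuron + 1L
  n_n <- if (is.null(n_neurons)) max(neuron, 1L) else as.integer(n_neurons)
  present <- sort(unique(neuron))
  if (length(present) > 0 && (max(present) > n_n || min(present) < 1L)) {
    abort("neuron indices exceed the declared number of neurons.")
  }
  if (is.null(n_neurons) && length(present) > 0 &&
      !all(seq_len(max(present)) %in% present)) {
    gaps <- setdiff(seq_len(max(present)), present)
    abort(paste0(
      "neuron indices must be dense; missing indices: ",
      paste(gaps - if (zero_based) 1L else 0L, collapse = ", ")
    ))
  }

  trial_ids <- sort(unique(events$trial))
  n_s <- max(length(trial_ids), 1L)
  trial_of <- match(events$trial, trial_ids)

  in_win <- events$time_ms >= window[1] & events$time_ms < window[2]
  dropped <- sum(!in_win)
  if (dropped > 0) {
    warning(sprintf("%d spike(s) outside the analysis window were dropped.", dropped))
  }

  counts <- array(0L, dim = c(n_s, n_t, n_n))
  if (any(in_win)) {
    bin <- floor((events$time_ms[in_win] - window[1]) / bin_width) + 1L
    tab <- table(
      factor(trial_of[in_win], levels = seq_len(n_s)),
      factor(bin, levels = seq_len(n_t)),
      factor(neuron[in_win], levels = seq_len(n_n))
    )
    counts <- array(as.integer(tab), dim = dim(counts))
  }

  labels <- if (nrow(events) > 0) {
    vapply(trial_ids, function(id) {
      as.character(events$stimulus[match(id, events$trial)])
    }, character(1))
  } else {
    rep("none", n_s)
  }
  out <- trial_tensor(counts, bin_width, window, labels)
  attr(out, "dropped") <- dropped
  out
}

#' Matricize a trial tensor for spatiotemporal decomposition
#'
#' Flattens each trial's `T x N` count matrix into one row of an
#' `S x (T * N)` matrix using time-major order: all neurons of bin 1, then
#' all neurons of bin 2, and so on. [tensorize_spatiotemporal()] inverts the
#' operation exactly.
#'
#' @param tensor a [trial_tensor()].
#' @return numeric matrix `S x (T * N)`.
#' @export
matricize_spatiotemporal <- function(tensor) {
  d <- dim(tensor$counts)
  # aperm to (N, T, S); column-major flatten makes neuron fastest within bin.
  m <- matrix(aperm(tensor$counts, c(3, 2, 1)), nrow = d[3] * d[2], ncol = d[1])
  t(m)
}

#' Inverse of [matricize_spatiotemporal()]
#'
#' @param mat matrix `S x (T * N)` in time-major order.
#' @param n_bins,n_neurons tensor dimensions.
#' @param bin_width,window,labels metadata for the rebuilt [trial_tensor()].
#' @return A [trial_tensor()].
#' @export
tensorize_spatiotemporal <- function(mat, n_bins, n_neurons, bin_width = 10,
                                     window = c(0, n_bins * bin_width),
                                     labels = rep("none", nrow(mat))) {
  if (ncol(mat) != n_bins * n_neurons) {
    abort("column count must equal n_bins * n_neurons.")
  }
  arr <- array(t(mat), dim = c(n_neurons, n_bins, nrow(mat)))
  trial_tensor(aperm(arr, c(3, 2, 1)), bin_width, window, labels)
}

# Reshape a single time-major row vector back to a T x N module matrix.
row_to_module <- function(v, n_bins, n_neurons) {
  matrix(v, nrow = n_bins, ncol = n_neurons, byrow = TRUE)
}

module_to_row <- function(m) as.vector(t(m))

#' Matricize a trial tensor for space-only decomposition
#'
#' Stacks the `T x N` trial matrices vertically into an `(S * T) x N` matrix
#' with (trial, bin)-major row order: row `(s - 1) * T + t` holds the counts
#' of all neurons in bin `t` of trial `s`. The operation is invertible.
#'
#' @param tensor a [trial_tensor()].
#' @return numeric matrix `(S * T) x N`.
#' @export
matricize_spatial <- function(tensor) {
  d <- dim(tensor$counts)
  # aperm to (T, S, N): flattening first two dims gives t fastest within s.
  matrix(aperm(tensor$counts, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

#' Inverse of [matricize_spatial()]
#'
#' @param mat matrix `(S * T) x N`.
#' @param n_trials number of trials `S`.
#' @inheritParams tensorize_spatiotemporal
#' @return A [trial_tensor()].
#' @export
tensorize_spatial <- function(mat, n_trials, bin_width = 10,
                              window = NULL,
                              labels = rep("none", n_trials)) {
  n_t <- nrow(mat) / n_trials
  if (n_t != round(n_t)) abort("row count must be a multiple of n_trials.")
  n_t <- as.integer(n_t)
  if (is.null(window)) window <- c(0, n_t * bin_width)
  arr <- array(mat, dim = c(n_t, n_trials, ncol(mat)))
  trial_tensor(aperm(arr, c(2, 1, 3)), bin_width, window, labels)
}

#' Tidy a trial tensor into a long tibble
#'
#' @param x a [trial_tensor()].
#' @param ... unused.
#' @return tibble with columns trial, stimulus, bin, time_ms, neuron, count.
#' @method tidy trial_tensor
#' @export
tidy.trial_tensor <- function(x, ...) {
  d <- dim(x$counts)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    stimulus = rep(as.character(x$labels), times = d[2] * d[3]),
    bin = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    neuron = rep(seq_len(d[3]), each = d[1] * d[2]),
    count = as.vector(x$counts)
  ) |>
    dplyr::mutate(time_ms = x$window[1] + (.data$bin - 0.5) * x$bin_width) |>
    dplyr::relocate("time_ms", .after = "bin")
}
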