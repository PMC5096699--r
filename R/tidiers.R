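#' @importFrom rlang .data
NULL

#' Tidy a space-by-time decomposition
#'
#' @param x an `sbt_decomp`.
#' @param ... unused.
#' @return tibble with one row per module element: columns `module_type`
#'   (`"temporal"`/`"spatial"`), `module`, `position` (bin or neuron index)
#'   and `value`.
#' @method tidy sbt_decomp
#' @export
tidy.sbt_decomp <- function(x, ...) {
  p <- ncol(x$temporal_modules)
  l <- nrow(x$spatial_modules)
  tt <- nrow(x$temporal_modules)
  nn <- ncol(x$spatial_modules)
  dplyr::bind_rows(
    tibble::tibble(
      module_type = "temporal",
      module = rep(seq_len(p), each = tt),
      position = rep(seq_len(tt), times = p),
      value = as.vector(x$temporal_modules)
    ),
    tibble::tibble(
      module_type = "spatial",
      module = rep(seq_len(l), times = nn),
      position = rep(seq_len(nn), each = l),
      value = as.vector(x$spatial_modules)
    )
  )
}

#' @rdname tidy.sbt_decomp
#' @method glance sbt_decomp
#' @export
glance.sbt_decomp <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_temporal = ncol(x$temporal_modules),
    n_spatial = nrow(x$spatial_modules),
    n_trials = dim(x$core)[1],
    reconstruction_error = x$reconstruction_error,
    iterations = x$iterations
  )
}

#' Tidy a spatiotemporal decomposition
#'
#' @param x an `st_decomp`.
#' @param ... unused.
#' @return tibble with columns `module`, `bin`, `neuron`, `value`.
#' @method tidy st_decomp
#' @export
tidy.st_decomp <- function(x, ...) {
  d <- dim(x$modules[[1]])
  purrr::map_dfr(seq_along(x$modules), function(k) {
    tibble::tibble(
      module = k,
      bin = rep(seq_len(d[1]), times = d[2]),
      neuron = rep(seq_len(d[2]), each = d[1]),
      value = as.vector(x$modules[[k]])
    )
  })
}

#' @rdname tidy.st_decomp
#' @method glance st_decomp
#' @export
glance.st_decomp <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_modules = length(x$modules),
    n_trials = nrow(x$activations),
    reconstruction_error = x$reconstruction_error,
    iterations = x$iterations
  )
}

#' Tidy a decoding result into a long confusion table
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return tibble with columns `truth`, `predicted`, `n`.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  cm <- as.table(x$confusion)
  tibble::tibble(
    truth = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    n = as.vector(cm)
  )
}

#' @rdname tidy.decoding_result
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_test = sum(x$confusion),
    n_stimuli = nrow(x$confusion),
    chance = 100 / nrow(x$confusion),
    n_dropped_coeffs = length(x$dropped)
  )
}

#' Plot the temporal and spatial modules of a space-by-time decomposition
#'
#' @param object an `sbt_decomp`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sbt_decomp
#' @export
autoplot.sbt_decomp <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::mutate(
      panel = ifelse(.data$module_type == "temporal",
                     paste0("temporal ", .data$module),
                     paste0("spatial ", .data$module)),
      axis = ifelse(.data$module_type == "temporal", "time bin", "neuron")
    )
  ggplot2::ggplot(td, ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "time bin / neuron", y = "module amplitude") +
    ggplot2::theme_minimal()
}

#' Plot spatiotemporal modules as time-by-neuron heat maps
#'
#' @param object an `st_decomp`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot st_decomp
#' @export
autoplot.st_decomp <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$bin, .data$neuron, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~module) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time bin", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      title = sprintf("accuracy %.1f%%", object$accuracy),
      x = "predicted stimulus", y = "true stimulus"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ground-truth rate patterns
#'
#' @param object a `rate_patterns` object.
#' @param ... unused.
#' @return a ggplot of one heat map per pattern.
#' @method autoplot rate_patterns
#' @export
autoplot.rate_patterns <- function(object, ...) {
  d <- dim(object$patterns[[1]])
  td <- purrr::map_dfr(seq_along(object$patterns), function(k) {
    tibble::tibble(
      pattern = k,
      bin = rep(seq_len(d[1]), times = d[2]),
      neuron = rep(seq_len(d[2]), each = d[1]),
      rate = as.vector(object$patterns[[k]])
    )
  })
  ggplot2::ggplot(td, ggplot2::aes(.data$bin, .data$neuron, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::scale_fill_viridis_c(name = "rate (Hz)") +
    ggplot2::labs(x = "time bin", y = "neuron") +
    ggplot2::theme_minimal()
}
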