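#' Run a simulation experiment grid
#'
#' Orchestrates the validation workflow end to end: for every cell of the
#' grid (preset x SNR x overlap level x trials per stimulus x model x seed)
#' it simulates a dataset, fits the requested decomposition, and evaluates
#' module recovery similarity against the generating patterns and/or test-set
#' decoding accuracy. Results accumulate in a tidy tibble with one row per
#' cell carrying full provenance (all cell parameters plus the seed), so a
#' rerun with the same configuration reproduces the table exactly.
#'
#' @param config named list with elements:
#'   `preset` (character vector of pattern presets),
#'   `snr` (numeric vector of foreground/background ratios),
#'   `level` (overlap levels, used by the `"overlap"` preset),
#'   `n_trials` (trials: total for mixture presets, per stimulus otherwise),
#'   `model` (character vector of model tags, see [select_module_numbers()]),
#'   `counts` (named list of module counts per model tag, e.g.
#'     `list("sbt-nmf" = list(p = 2, l = 2), "st-nmf" = list(k = 4))`),
#'   `seeds` (integer vector),
#'   `background_rate` (Hz, default 2),
#'   `measure` (`"recovery"`, `"decoding"` or both),
#'   `n_train` (training trials per stimulus for decoding),
#'   `opts` (fitting options, see [decode_pipeline()]).
#' @param out optional CSV path; the table is appended/written there.
#' @param verbose print one line per cell?
#' @return tibble with columns preset, snr, level, n_trials, model, seed,
#'   measure, value.
#' @export
run_experiment <- function(config, out = NULL, verbose = FALSE) {
  cfg <- utils::modifyList(
    list(
      preset = "separable", snr = 150, level = 0, n_trials = 900,
      model = "sbt-nmf", counts = list(), seeds = 1L,
      background_rate = 2, measure = "recovery", n_train = NULL,
      opts = list()
    ),
    config
  )
  cells <- expand.grid(
    preset = cfg$preset, snr = cfg$snr, level = cfg$level,
    n_trials = cfg$n_trials, model = cfg$model, seed = cfg$seeds,
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    res <- tryCatch(
      run_cell(cell, cfg),
      error = function(e) {
        warning(sprintf("cell %d failed: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    if (verbose) {
      message(sprintf("[%d/%d] %s snr=%g model=%s seed=%d",
                      i, nrow(cells), cell$preset, cell$snr, cell$model,
                      cell$seed))
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

run_cell <- function(cell, cfg) {
  pats <- make_block_patterns(
    cell$preset, fg_rate = cell$snr * cfg$background_rate,
    bg_rate = cfg$background_rate, level = cell$level
  )
  tensor <- generate_trials(pats, n_trials = cell$n_trials, seed = cell$seed)
  counts <- cfg$counts[[cell$model]]
  if (is.null(counts)) {
    counts <- if (cell$model %in% c("sbt-nmf", "tucker2")) {
      list(p = 2, l = 2)
    } else {
      list(k = length(pats$patterns))
    }
  }
  out <- list()
  if ("recovery" %in% cfg$measure) {
    fit <- fit_model(tensor, cell$model, counts, seed = cell$seed,
                     opts = cfg$opts)$fit
    signed <- cell$model %in% c("st-pca", "st-ica", "st-fa", "tucker2")
    out$recovery <- module_set_similarity(fit, pats, signed = signed)
  }
  if ("decoding" %in% cfg$measure) {
    n_train <- cfg$n_train %||% floor(cell$n_trials / 2)
    out$decoding <- decode_pipeline(
      tensor, cell$model, counts, n_train, seed = cell$seed, opts = cfg$opts
    )$accuracy
  }
  purrr::map_dfr(names(out), function(m) {
    tibble::tibble(
      preset = cell$preset, snr = cell$snr, level = cell$level,
      n_trials = cell$n_trials, model = cell$model, seed = cell$seed,
      measure = m, value = out[[m]]
    )
  })
}
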