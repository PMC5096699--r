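#' Stratified train/test split of a trial tensor
#'
#' Randomly assigns `n_train` trials of every stimulus to the training set
#' and all remaining trials to the test set (e.g. 30 trials per stimulus with
#' `n_train = 15` gives a 15/15 split; 19 trials with `n_train = 10` gives
#' 10/9). Reproducible under a fixed seed.
#'
#' @param tensor a [trial_tensor()].
#' @param n_train training trials per stimulus; every stimulus must have at
#'   least `n_train + 1` trials.
#' @param seed RNG seed.
#' @return list with `train` and `test` trial tensors and the index vectors
#'   `train_idx` / `test_idx`.
#' @export
train_test_split <- function(tensor, n_train, seed = NULL) {
  n_train <- assert_scalar_count(n_train, "n_train")
  labs <- tensor$labels
  counts <- table(labs)
  short <- names(counts)[counts < n_train + 1]
  if (length(short) > 0) {
    abort(paste0(
      "stimuli with fewer than n_train + 1 trials: ",
      paste(short, collapse = ", ")
    ))
  }
  with_seed(seed, {
    train_idx <- integer(0)
    for (lv in levels(labs)) {
      idx <- which(labs == lv)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(labs), train_idx)
    list(
      train = tensor_subset(tensor, train_idx),
      test = tensor_subset(tensor, test_idx),
      train_idx = train_idx, test_idx = test_idx
    )
  })
}

#' Decoding result
#'
#' @param accuracy percent correct on the test set.
#' @param confusion confusion matrix (rows = true stimulus, columns =
#'   predicted); each row sums to that stimulus's test-trial count.
#' @param selected selected module counts, if selection was run.
#' @param split split bookkeeping (seed, trials per stimulus).
#' @param dropped indices of zero-variance coefficients removed before LDA.
#' @return object of class `decoding_result`.
#' @keywords internal
new_decoding_result <- function(accuracy, confusion, selected = NULL,
                                split = NULL, dropped = integer(0)) {
  structure(
    list(accuracy = accuracy, confusion = confusion, selected = selected,
         split = split, dropped = dropped),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.2f%% over %d test trials (%d stimuli)\n",
              x$accuracy, sum(x$confusion), nrow(x$confusion)))
  if (!is.null(x$selected)) {
    cat("  selected module counts:",
        paste(names(x$selected), unlist(x$selected), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Multiclass LDA with pooled within-class covariance; a ridge
# (1e-6 * trace / d, escalated if needed) is added whenever the pooled
# covariance is singular, as with raw high-dimensional spike-count features.
lda_fit <- function(x, labels, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) abort("LDA needs at least 2 classes.")
  if (any(table(labels) < 2)) {
    abort("every class needs at least 2 training trials.")
  }
  keep <- which(apply(x, 2, function(col) var(col) > 0))
  if (length(keep) == 0) abort("all predictors have zero variance.")
  dropped <- setdiff(seq_len(ncol(x)), keep)
  x <- x[, keep, drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  cls <- levels(labels)
  means <- do.call(rbind, lapply(cls, function(cl) colMeans(x[labels == cl, , drop = FALSE])))
  centered <- x - means[as.integer(labels), , drop = FALSE]
  sw <- crossprod(centered) / (n - length(cls))
  lambda <- 0
  ch <- NULL
  repeat {
    ch <- tryCatch(chol(sw + diag(lambda, p)), error = function(e) NULL)
    if (!is.null(ch) && kappa(ch, exact = FALSE) < 1e10) break
    lambda <- if (lambda == 0) ridge * sum(diag(sw)) / p else lambda * 100
    if (lambda > 1e6 * (sum(diag(sw)) / p + 1)) {
      ch <- chol(sw + diag(lambda, p))
      break
    }
  }
  sw_inv_means <- backsolve(ch, forwardsolve(t(ch), t(means)))  # p x C
  const <- -0.5 * colSums(t(means) * sw_inv_means) +
    log(as.numeric(table(labels)) / n)
  structure(
    list(w = sw_inv_means, const = const, classes = cls, keep = keep,
         dropped = dropped, lambda = lambda),
    class = "poptensor_lda"
  )
}

#' @export
predict.poptensor_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$keep, drop = FALSE]
  scores <- x %*% object$w + matrix(object$const, nrow(x), length(object$const),
                                    byrow = TRUE)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Decode stimuli from activation coefficients with multiclass LDA
#'
#' Removes coefficients with zero variance across all training trials (from
#' both sets), fits pooled-covariance LDA (ridge-regularized when the pooled
#' covariance is singular) on the training coefficients, and reports percent
#' correct on the test set.
#'
#' @param train_coeffs,test_coeffs coefficient matrices (trials x
#'   coefficients); 3-way coefficient arrays are flattened per trial.
#' @param train_labels,test_labels stimulus labels.
#' @return a `decoding_result`.
#' @export
lda_decode <- function(train_coeffs, train_labels, test_coeffs, test_labels) {
  train_coeffs <- flatten_coeffs(train_coeffs)
  test_coeffs <- flatten_coeffs(test_coeffs)
  fit <- lda_fit(train_coeffs, train_labels)
  truth <- factor(as.character(test_labels), levels = fit$classes)
  pred <- predict(fit, test_coeffs)
  confusion <- table(truth = truth, predicted = pred)
  new_decoding_result(
    accuracy = 100 * mean(pred == truth),
    confusion = unclass(confusion),
    dropped = fit$dropped
  )
}

flatten_coeffs <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    return(matrix(x, d[1], d[2] * d[3]))
  }
  as.matrix(x)
}

#' Raw-LDA baseline: decode from binned spike counts directly
#'
#' Flattens each trial's `T x N` spike-count matrix into a `T * N` vector and
#' applies [lda_decode()] without any dimensionality reduction.
#'
#' @param train,test [trial_tensor()] objects.
#' @return a `decoding_result`.
#' @export
raw_lda <- function(train, test) {
  lda_decode(
    matricize_spatiotemporal(train), train$labels,
    matricize_spatiotemporal(test), test$labels
  )
}

# Fit the requested model on a tensor and return (fit, train activations).
fit_model <- function(tensor, model, counts, seed = NULL, opts = list()) {
  o <- utils::modifyList(
    list(max_iter = 500, tol = 1e-6, n_restarts = 2), opts
  )
  switch(model,
    "sbt-nmf" = {
      fit <- space_by_time_nmf(tensor, counts$p, counts$l, o$max_iter, o$tol,
                               o$n_restarts, seed)
      list(fit = fit, coeffs = flatten_coeffs(fit$core))
    },
    "tucker2" = {
      fit <- orthogonal_tucker2(tensor, counts$p, counts$l)
      list(fit = fit, coeffs = flatten_coeffs(fit$core))
    },
    "st-nmf" = {
      fit <- spatiotemporal_nmf(tensor, counts$k, o$max_iter, o$tol,
                                o$n_restarts, seed)
      list(fit = fit, coeffs = fit$activations)
    },
    "st-pca" = ,
    "st-ica" = ,
    "st-fa" = {
      method <- sub("^st-", "", model)
      fit <- spatiotemporal_linear(tensor, counts$k, method, seed)
      list(fit = fit, coeffs = fit$activations)
    },
    abort(sprintf("unknown model: %s", model))
  )
}

model_infer <- function(fit, tensor, seed = NULL) {
  if (inherits(fit, "sbt_decomp")) {
    flatten_coeffs(infer_core(fit, tensor, seed = seed))
  } else {
    infer_activations(fit, tensor, seed = seed)
  }
}

#' Leave-one-out selection of the number of modules
#'
#' For every candidate module count, one trial per stimulus is held out of
#' the training set as a validation fold; modules are fit on the remaining
#' trials, validation coefficients are inferred with frozen modules, and LDA
#' decodes the validation trials. Fold-averaged accuracies drive the
#' selection: the candidate with maximum mean validation accuracy wins, ties
#' broken by minimum total module count, then by minimum `p`, then `l`.
#'
#' @param train a training [trial_tensor()] with at least 3 trials per
#'   stimulus.
#' @param model `"sbt-nmf"`, `"tucker2"`, `"st-nmf"`, `"st-pca"`, `"st-ica"`
#'   or `"st-fa"`.
#' @param grid candidate counts: a data frame with columns `p`, `l` (tensor
#'   models) or a vector/data frame of `k` (matrix models).
#' @param seed RNG seed.
#' @param opts list overriding fitting options (`max_iter`, `tol`,
#'   `n_restarts`).
#' @return list with `selected` (named list of counts) and `grid` (a tibble
#'   of candidates and mean validation accuracies).
#' @export
select_module_numbers <- function(train, model, grid, seed = NULL,
                                  opts = list()) {
  tensor_model <- model %in% c("sbt-nmf", "tucker2")
  if (tensor_model) {
    grid <- as.data.frame(grid)
    if (!all(c("p", "l") %in% names(grid)) || nrow(grid) == 0) {
      abort("`grid` must be a non-empty data frame with columns p and l.")
    }
  } else {
    if (is.data.frame(grid)) grid <- grid$k
    if (length(grid) == 0) abort("`grid` must be non-empty.")
    grid <- data.frame(k = as.integer(grid))
  }
  labs <- train$labels
  per_stim <- split(seq_along(labs), labs)
  n_folds <- min(lengths(per_stim))
  if (n_folds < 3) abort("selection needs at least 3 training trials per stimulus.")
  seeds <- derive_seeds(seed, nrow(grid) * n_folds)
  acc <- matrix(NA_real_, n_folds, nrow(grid))
  # hold out the f-th trial of every stimulus (per-stimulus order is as given)
  for (f in seq_len(n_folds)) {
    val_idx <- vapply(per_stim, function(ix) ix[f], integer(1))
    fit_idx <- setdiff(seq_along(labs), val_idx)
    fit_tensor <- tensor_subset(train, fit_idx)
    val_tensor <- tensor_subset(train, val_idx)
    for (g in seq_len(nrow(grid))) {
      sd_g <- seeds[[(g - 1L) * n_folds + f]]
      counts <- as.list(grid[g, , drop = FALSE])
      fit <- fit_model(fit_tensor, model, counts, seed = sd_g, opts = opts)
      val_coeffs <- model_infer(fit$fit, val_tensor, seed = sd_g)
      res <- lda_decode(fit$coeffs, fit_tensor$labels, val_coeffs,
                        val_tensor$labels)
      acc[f, g] <- res$accuracy
    }
  }
  mean_acc <- colMeans(acc)
  total <- if (tensor_model) grid$p + grid$l else grid$k
  second <- if (tensor_model) grid$p else grid$k
  third <- if (tensor_model) grid$l else grid$k
  ord <- order(-mean_acc, total, second, third)
  best <- ord[1]
  list(
    selected = as.list(grid[best, , drop = FALSE]),
    grid = tibble::tibble(grid, mean_accuracy = mean_acc)
  )
}

#' Full decomposition-based decoding pipeline
#'
#' Splits trials per stimulus, fits the decomposition on the training set
#' only (optionally selecting module counts by leave-one-out validation
#' within the training set), infers test-set coefficients with frozen
#' modules, and decodes the test stimuli with LDA. No information from the
#' test set enters module fitting, coefficient selection or classifier
#' training.
#'
#' @param tensor a [trial_tensor()] with at least 2 stimuli.
#' @param model see [select_module_numbers()].
#' @param counts named list of module counts (`p`, `l` or `k`), or `"auto"`
#'   to select them with [select_module_numbers()] on `grid`.
#' @param n_train training trials per stimulus.
#' @param seed RNG seed driving the split, fits and selection.
#' @param grid candidate grid when `counts = "auto"`.
#' @param opts fitting options passed through.
#' @return a `decoding_result` with the selected counts and split descriptor.
#' @export
decode_pipeline <- function(tensor, model, counts, n_train, seed = NULL,
                            grid = NULL, opts = list()) {
  if (nlevels(tensor$labels) < 2) abort("decoding needs at least 2 stimuli.")
  seeds <- derive_seeds(seed, 3)
  split <- train_test_split(tensor, n_train, seed = seeds[[1]])
  if (identical(counts, "auto")) {
    if (is.null(grid)) abort("`counts = \"auto\"` requires a `grid`.")
    sel <- select_module_numbers(split$train, model, grid, seed = seeds[[2]],
                                 opts = opts)
    counts <- sel$selected
  }
  fit <- fit_model(split$train, model, counts, seed = seeds[[3]], opts = opts)
  test_coeffs <- model_infer(fit$fit, split$test, seed = seeds[[3]])
  res <- lda_decode(fit$coeffs, split$train$labels, test_coeffs,
                    split$test$labels)
  res$selected <- counts
  res$split <- list(seed = seed, n_train = n_train,
                    n_test = length(split$test_idx) / nlevels(tensor$labels))
  res
}

#' Generalization of modules to unseen stimuli
#'
#' Stimuli are split into a module-training pool (set B) and a held-out set A
#' used only for decoding. Modules are fit on the training trials of `n`
#' set-B stimuli; activation coefficients are then inferred for all set-A
#' trials, and an LDA classifier is trained on set-A training trials and
#' scored on set-A test trials. With `n` covering all stimuli and an empty
#' held-out set the procedure reduces to [decode_pipeline()].
#'
#' @param tensor a [trial_tensor()].
#' @param model,counts,n_train,seed,opts as in [decode_pipeline()].
#' @param n_module_stimuli vector of set-B stimulus counts to evaluate.
#' @param set_b_size size of the module-training pool (default
#'   `max(n_module_stimuli)`); the remaining stimuli form set A.
#' @return tibble with columns `n_module_stimuli` and `accuracy`.
#' @export
generalization_experiment <- function(tensor, model, counts, n_train,
                                      n_module_stimuli, set_b_size = NULL,
                                      seed = NULL, opts = list()) {
  stims <- levels(tensor$labels)
  set_b_size <- set_b_size %||% max(n_module_stimuli)
  if (set_b_size > length(stims)) abort("set B exceeds the number of stimuli.")
  if (max(n_module_stimuli) > set_b_size) {
    abort("`n_module_stimuli` exceeds the set-B size.")
  }
  seeds <- derive_seeds(seed, 3 + length(n_module_stimuli))
  set_b <- with_seed(seeds[[1]], sample(stims, set_b_size))
  set_a <- setdiff(stims, set_b)
  if (length(set_a) == 0) set_a <- stims   # degenerate: sets coincide
  split <- train_test_split(tensor, n_train, seed = seeds[[2]])
  a_train <- tensor_subset(split$train, which(split$train$labels %in% set_a))
  a_test <- tensor_subset(split$test, which(split$test$labels %in% set_a))
  purrr::map_dfr(seq_along(n_module_stimuli), function(i) {
    n <- n_module_stimuli[i]
    sd_i <- seeds[[3 + i]]
    b_used <- with_seed(sd_i, sample(set_b, n))
    b_train <- tensor_subset(split$train, which(split$train$labels %in% b_used))
    fit <- fit_model(b_train, model, counts, seed = sd_i, opts = opts)
    res <- lda_decode(
      model_infer(fit$fit, a_train, seed = sd_i), a_train$labels,
      model_infer(fit$fit, a_test, seed = sd_i), a_test$labels
    )
    tibble::tibble(n_module_stimuli = n, accuracy = res$accuracy)
  })
}

#' Rank-order decoding from first-spike latencies
#'
#' Per trial, neurons are ranked by their first-spike latency (ties get
#' average ranks; neurons that stay silent share the maximal rank). Each
#' stimulus's template is the mean training rank vector; a test trial is
#' assigned to the template with the highest rank correlation, ties broken
#' deterministically toward the smallest stimulus label. An all-silent test
#' trial correlates equally with every template and falls to the tie-break.
#'
#' @param events spike-event data frame (see [bin_spikes()]).
#' @param window analysis window in ms.
#' @param n_train training trials per stimulus.
#' @param n_neurons population size (defaults to the largest index present).
#' @param seed RNG seed for the split.
#' @return a `decoding_result`.
#' @export
rank_order_decode <- function(events, window = c(0, 300), n_train,
                              n_neurons = NULL, seed = NULL) {
  lat <- first_spike_latencies(events, window, n_neurons)
  ranks <- t(apply(lat, 1, rank))   # average ranks; Inf latencies share max
  labels <- attr(lat, "labels")
  tmp_tensor <- trial_tensor(
    array(0L, dim = c(nrow(ranks), 1, ncol(ranks))), bin_width = diff(window),
    window = window, labels = labels
  )
  split <- train_test_split(tmp_tensor, n_train, seed = seed)
  classes <- levels(labels)
  templates <- do.call(rbind, lapply(classes, function(cl) {
    idx <- intersect(split$train_idx, which(labels == cl))
    colMeans(ranks[idx, , drop = FALSE])
  }))
  if (any(apply(templates, 1, sd) == 0 &
          vapply(classes, function(cl) {
            all(is.infinite(lat[intersect(split$train_idx, which(labels == cl)), ]))
          }, logical(1)))) {
    abort("all neurons silent in all training trials of a class.")
  }
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  pred <- vapply(split$test_idx, function(i) {
    cors <- apply(templates, 1, function(tmpl) safe_cor(ranks[i, ], tmpl))
    classes[which.max(cors)]   # which.max takes the first (smallest label) tie
  }, character(1))
  truth <- factor(labels[split$test_idx], levels = classes)
  pred <- factor(pred, levels = classes)
  confusion <- table(truth = truth, predicted = pred)
  new_decoding_result(100 * mean(pred == truth), unclass(confusion),
                      split = list(seed = seed, n_train = n_train))
}

# Per-trial first-spike latency matrix (trials x neurons; Inf = silent).
first_spike_latencies <- function(events, window, n_neurons = NULL) {
  stopifnot(is.data.frame(events))
  keep <- events$time_ms >= window[1] & events$time_ms < window[2]
  events <- events[keep, , drop = FALSE]
  trial_ids <- sort(unique(events$trial))
  neuron <- as.integer(events$neuron)
  if (length(neuron) > 0 && min(neuron) == 0L) neuron <- neuron + 1L
  n_n <- n_neurons %||% max(neuron, 1L)
  lat <- matrix(Inf, length(trial_ids), n_n)
  for (r in seq_len(nrow(events))) {
    i <- match(events$trial[r], trial_ids)
    j <- neuron[r]
    lat[i, j] <- min(lat[i, j], events$time_ms[r])
  }
  labels <- factor(vapply(trial_ids, function(id) {
    as.character(events$stimulus[match(id, events$trial)])
  }, character(1)))
  attr(lat, "labels") <- labels
  lat
}
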