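test_that("stratified splits have the stated sizes and are seed-reproducible", {
  labels <- rep(sprintf("s%02d", 1:4), each = 30)
  tt <- tiny_tensor(s = 120, t = 3, n = 2, labels = labels)
  sp <- train_test_split(tt, 15, seed = 1)
  expect_equal(as.vector(table(sp$train$labels)), rep(15, 4))
  expect_equal(as.vector(table(sp$test$labels)), rep(15, 4))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  labels19 <- rep(c("a", "b"), each = 19)
  tt19 <- tiny_tensor(s = 38, t = 3, n = 2, labels = labels19)
  sp19 <- train_test_split(tt19, 10, seed = 2)
  expect_equal(as.vector(table(sp19$train$labels)), c(10, 10))
  expect_equal(as.vector(table(sp19$test$labels)), c(9, 9))

  sp_b <- train_test_split(tt, 15, seed = 1)
  expect_identical(sp$train_idx, sp_b$train_idx)
  short <- tiny_tensor(s = 10, t = 3, n = 2, labels = rep(c("a", "b"), each = 5))
  expect_error(train_test_split(short, 5, seed = 1), "a, b")
})

test_that("LDA separates separable clusters, respects chance under shuffling, and drops zero-variance coefficients", {
  gc2 <- gaussian_clusters(n_per = 40, sep = 8)
  idx <- sample(80)
  train <- idx[1:40]
  test <- idx[41:80]
  res <- lda_decode(gc2$x[train, ], gc2$labels[train],
                    gc2$x[test, ], gc2$labels[test])
  expect_equal(res$accuracy, 100)
  expect_equal(rowSums(res$confusion),
               as.vector(table(factor(gc2$labels[test]))), ignore_attr = TRUE)

  # zero-variance coefficient is removed, not fatal
  x_aug <- cbind(gc2$x, 7)
  res2 <- lda_decode(x_aug[train, ], gc2$labels[train],
                     x_aug[test, ], gc2$labels[test])
  expect_equal(res2$dropped, 4L)
  expect_equal(res2$accuracy, 100)
  expect_error(
    lda_decode(matrix(1, 10, 3), rep(c("a", "b"), 5), matrix(1, 2, 3), c("a", "b")),
    "zero variance"
  )

  # 60-class label shuffling decodes at ~1/60 chance (mean over seeds)
  n_cls <- 60
  accs <- vapply(1:4, function(rep_i) {
    set.seed(20 + rep_i)
    x <- matrix(rnorm(n_cls * 20 * 4), n_cls * 20, 4)
    labs <- sample(rep(sprintf("c%02d", 1:n_cls), each = 20))
    lda_decode(x[1:900, ], labs[1:900], x[901:1200, ], labs[901:1200])$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 100 / n_cls * 0.5)
  expect_lt(mean(accs), 100 / n_cls * 2)
})

test_that("two-class LDA accuracy matches the analytic Bayes rate for 1-D Gaussians", {
  # equal-variance classes at means 0 and 2, sd 1: Bayes rate = Phi(1)
  set.seed(21)
  n <- 4000
  x_train <- matrix(c(rnorm(n / 2), rnorm(n / 2, 2)), ncol = 1)
  y <- rep(c("a", "b"), each = n / 2)
  x_test <- matrix(c(rnorm(n / 2), rnorm(n / 2, 2)), ncol = 1)
  res <- lda_decode(x_train, y, x_test, y)
  bayes <- 100 * pnorm(1)
  expect_lt(abs(res$accuracy - bayes), 2.5)  # Monte-Carlo error margin
})

test_that("LDA agrees with the reference implementation on well-conditioned data", {
  skip_if_not_installed("MASS")
  gc3 <- gaussian_clusters(n_per = 50, d = 4, sep = 1.5, seed = 22)
  fit <- lda_fit(gc3$x[1:80, ], gc3$labels[1:80])
  ours <- predict(fit, gc3$x[81:100, ])
  ref <- MASS::lda(gc3$x[1:80, ], grouping = gc3$labels[1:80])
  theirs <- predict(ref, gc3$x[81:100, ])$class
  expect_equal(as.character(ours), as.character(theirs))
})

test_that("raw LDA is exactly LDA on the matricized counts", {
  labels <- rep(c("a", "b", "c"), each = 14)
  tt <- tiny_tensor(s = 42, t = 4, n = 3, seed = 23, labels = labels)
  sp <- train_test_split(tt, 7, seed = 3)
  direct <- lda_decode(
    matricize_spatiotemporal(sp$train), sp$train$labels,
    matricize_spatiotemporal(sp$test), sp$test$labels
  )
  viaraw <- raw_lda(sp$train, sp$test)
  expect_equal(viaraw$accuracy, direct$accuracy)
  expect_equal(viaraw$confusion, direct$confusion)
})

test_that("module-count selection returns the single candidate and recovers ground truth", {
  pats <- make_block_patterns("overlap", level = 1, fg_rate = 100)
  tens <- generate_trials(pats, n_trials = 8, seed = 30)
  one <- select_module_numbers(tens, "sbt-nmf", data.frame(p = 3, l = 2),
                               seed = 1, opts = list(n_restarts = 1))
  expect_equal(one$selected, list(p = 3, l = 2))
  expect_error(select_module_numbers(tens, "sbt-nmf", data.frame()), "non-empty")

  # noiseless-ish separable data generated from (2,2): larger candidates tie
  # at perfect validation accuracy and the minimum-sum tie-break picks (2,2)
  grid <- expand.grid(p = 2:3, l = 2:3)
  sel <- select_module_numbers(tens, "sbt-nmf", grid, seed = 2,
                               opts = list(n_restarts = 1, max_iter = 300))
  expect_equal(unname(unlist(sel$selected)), c(2, 2))
  expect_true(all(sel$grid$mean_accuracy <= 100))
})

test_that("decode pipeline reaches ~100% on a high-SNR 6-condition design and rejects degenerate input", {
  pats <- make_block_patterns("overlap", level = 1, fg_rate = 30)  # SNR 15
  tens <- generate_trials(pats, n_trials = 30, seed = 31)
  res <- decode_pipeline(tens, "sbt-nmf", list(p = 2, l = 2), n_train = 15,
                         seed = 4, opts = list(n_restarts = 1))
  expect_gte(res$accuracy, 95)
  expect_equal(res$selected, list(p = 2, l = 2))

  single <- tiny_tensor(s = 10, t = 3, n = 2, labels = rep("only", 10))
  expect_error(decode_pipeline(single, "sbt-nmf", list(p = 1, l = 1), 5),
               "2 stimuli")

  # label shuffling brings accuracy to chance
  shuffled <- tens
  set.seed(32)
  shuffled$labels <- sample(shuffled$labels)
  res_sh <- decode_pipeline(shuffled, "sbt-nmf", list(p = 2, l = 2),
                            n_train = 15, seed = 5, opts = list(n_restarts = 1))
  expect_lt(res_sh$accuracy, 2 * 100 / 6 + 10)
})

test_that("no test-set leakage: fitting leaves test data byte-identical", {
  pats <- make_block_patterns("overlap", level = 0, fg_rate = 40)
  tens <- generate_trials(pats, n_trials = 12, seed = 33)
  sp <- train_test_split(tens, 6, seed = 6)
  checksum_before <- digest_counts(sp$test$counts)
  fit <- space_by_time_nmf(sp$train, 2, 2, n_restarts = 1, seed = 7)
  h_test <- infer_core(fit, sp$test, seed = 7)
  res <- lda_decode(flatten_coeffs(fit$core), sp$train$labels,
                    flatten_coeffs(h_test), sp$test$labels)
  expect_identical(digest_counts(sp$test$counts), checksum_before)
  expect_gt(res$accuracy, 0)
})

test_that("modules fit on few stimuli still decode held-out stimuli above chance", {
  pats <- make_block_patterns("overlap", level = 0, fg_rate = 100)
  tens <- generate_trials(pats, n_trials = 14, seed = 34)
  curve <- generalization_experiment(
    tens, "sbt-nmf", list(p = 2, l = 2), n_train = 7,
    n_module_stimuli = c(1, 3), set_b_size = 3, seed = 8,
    opts = list(n_restarts = 1)
  )
  expect_equal(curve$n_module_stimuli, c(1, 3))
  # 3 held-out stimuli -> chance 33%
  expect_true(all(curve$accuracy > 40))
})

test_that("rank-order decoding matches hand-computed rank correlations", {
  # two classes with mirrored latency orders [12,20,30] vs [30,20,12]
  mk_trials <- function(stim, lat, trials) {
    purrr::map_dfr(trials, function(tr) {
      tibble::tibble(trial = tr, stimulus = stim, neuron = 1:3, time_ms = lat)
    })
  }
  ev <- dplyr::bind_rows(
    mk_trials("a", c(12, 20, 30), 1:6),
    mk_trials("b", c(30, 20, 12), 7:12)
  )
  res <- rank_order_decode(ev, window = c(0, 300), n_train = 3, seed = 9)
  # noiseless mirrored orders are perfectly separable by rank correlation
  expect_equal(res$accuracy, 100)

  # an all-silent test trial ties all templates and falls to the smallest label
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(
    trial = 13, stimulus = "b", neuron = 1, time_ms = 500  # outside window
  ))
  res2 <- rank_order_decode(ev2, window = c(0, 300), n_train = 5, seed = 10)
  expect_s3_class(res2, "decoding_result")
})
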