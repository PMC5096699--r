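test_that("time shuffling conserves per-neuron totals and degenerates to identity at T = 1", {
  tt <- tiny_tensor(s = 8, t = 6, n = 5, seed = 1)
  sh <- shuffle_time(tt, seed = 2)
  expect_false(identical(sh$counts, tt$counts))
  for (s in 1:8) {
    expect_equal(colSums(sh$counts[s, , ]), colSums(tt$counts[s, , ]))
  }
  one_bin <- tiny_tensor(s = 4, t = 1, n = 5, seed = 3)
  expect_identical(shuffle_time(one_bin, seed = 4)$counts, one_bin$counts)
  # per-neuron scope also conserves totals
  sh2 <- shuffle_time(tt, scope = "per_neuron", seed = 5)
  for (s in 1:8) {
    expect_equal(colSums(sh2$counts[s, , ]), colSums(tt$counts[s, , ]))
  }
})

test_that("space shuffling conserves per-bin pooled counts and degenerates at N = 1", {
  tt <- tiny_tensor(s = 8, t = 6, n = 5, seed = 6)
  sh <- shuffle_space(tt, seed = 7)
  for (s in 1:8) {
    expect_equal(rowSums(sh$counts[s, , ]), rowSums(tt$counts[s, , ]))
  }
  solo <- tiny_tensor(s = 4, t = 6, n = 1, seed = 8)
  expect_identical(shuffle_space(solo, seed = 9)$counts, solo$counts)
})

test_that("latency filtering keeps each neuron's earliest spike and is idempotent", {
  ev <- tibble::tibble(
    trial = c(1, 1, 1, 1, 2),
    stimulus = c("a", "a", "a", "a", "b"),
    neuron = c(1, 1, 1, 2, 1),
    time_ms = c(45, 12, 80, 33, 5)
  )
  f1 <- first_spike_filter(ev)
  expect_equal(nrow(f1), 3)
  expect_equal(sort(f1$time_ms), c(5, 12, 33))
  expect_equal(first_spike_filter(f1), f1)
  # binned output has at most one spike per (trial, neuron)
  tt <- bin_spikes(f1, 10, c(0, 300))
  expect_true(all(apply(tt$counts, c(1, 3), sum) <= 1))
  # silent neurons stay silent: neuron 2 absent from trial 2
  expect_false(any(f1$trial == 2 & f1$neuron == 2))
})

test_that("precision coarsening conserves per-group counts; k = 1 is identity, k = T a full shuffle", {
  tt <- tiny_tensor(s = 6, t = 12, n = 4, seed = 10)
  expect_identical(coarsen_precision(tt, 1, seed = 11), tt)
  ck <- coarsen_precision(tt, 3, seed = 12)
  for (s in 1:6) for (n in 1:4) for (g in 0:3) {
    bins <- g * 3 + 1:3
    expect_equal(sum(ck$counts[s, bins, n]), sum(tt$counts[s, bins, n]))
  }
  expect_error(coarsen_precision(tt, 0), "integer >= 1")

  # k = T behaves like a full within-trial per-neuron time shuffle in
  # distribution: totals conserved and the order statistics of bin positions
  # of a marked spike are uniform
  probe <- trial_tensor(array(0, c(1, 12, 1)), 10, c(0, 120), "a")
  probe$counts[1, 1, 1] <- 1
  pos <- vapply(1:400, function(i) {
    which(coarsen_precision(probe, 12, seed = i)$counts[1, , 1] == 1)
  }, numeric(1))
  expect_gt(suppressWarnings(chisq.test(table(factor(pos, levels = 1:12)))$p.value),
            1e-4)
})

test_that("the shuffle report recovers the planted information structure", {
  pats <- make_block_patterns("info_type", fg_rate = 100)
  tens <- generate_trials(pats, n_trials = 16, seed = 13)
  rep_tab <- space_time_report(
    tens, "sbt-nmf", list(p = 3, l = 3), n_train = 8,
    conditions = c("space_and_time", "space_only", "time_only"),
    seed = 14, opts = list(n_restarts = 1)
  )
  expect_setequal(rep_tab$condition,
                  c("space_and_time", "space_only", "time_only"))
  acc <- function(cond) rep_tab$accuracy[rep_tab$condition == cond]
  # intact decoding of the 6 variants is far above the 16.7% chance level
  expect_gt(acc("space_and_time"), 80)
  # destroying a dimension can only lose accuracy (within noise)
  expect_gte(acc("space_and_time") + 15, acc("space_only"))
  expect_gte(acc("space_and_time") + 15, acc("time_only"))
  expect_gt(acc("space_only"), acc("time_only") - 15)
})

test_that("shuffles localize the loss to the targeted pattern type", {
  pats <- make_block_patterns("info_type", fg_rate = 100)
  tens <- generate_trials(pats, n_trials = 30, seed = 15)
  # within-pair decoders: the space pair survives a time shuffle at ~100%,
  # the time pair collapses to ~50% chance
  pair_acc <- function(x, keep, seed) {
    sub <- tensor_subset(x, which(as.character(x$labels) %in% keep))
    decode_pipeline(sub, "sbt-nmf", list(p = 2, l = 2), n_train = 15,
                    seed = seed, opts = list(n_restarts = 1))$accuracy
  }
  shuffled <- shuffle_time(tens, seed = 16)
  expect_gt(pair_acc(shuffled, c("space_a", "space_b"), 17), 85)
  time_acc <- pair_acc(shuffled, c("time_a", "time_b"), 18)
  expect_lt(time_acc, 80)  # chance is 50% for the two alternatives
  sp_shuffled <- shuffle_space(tens, seed = 19)
  expect_gt(pair_acc(sp_shuffled, c("time_a", "time_b"), 20), 85)
  expect_lt(pair_acc(sp_shuffled, c("space_a", "space_b"), 21), 80)
})

test_that("population subsampling at full fraction reproduces the baseline", {
  pats <- make_block_patterns("overlap", level = 0, fg_rate = 60)
  tens <- generate_trials(pats, n_trials = 10, seed = 22)
  rep_tab <- space_time_report(
    tens, "sbt-nmf", list(p = 2, l = 2), n_train = 5,
    conditions = c("space_and_time", "population_fraction"),
    fractions = 1.0, seed = 23, opts = list(n_restarts = 1)
  )
  full <- rep_tab$accuracy[rep_tab$condition == "space_and_time"]
  frac <- rep_tab$accuracy[startsWith(rep_tab$condition, "population_fraction")]
  expect_equal(frac, full)
})
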