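make_rate_table <- function(arr) {
  structure(arr, class = c("rate_table", class(arr)))
}

test_that("spike counts convert to rates over the test windows", {
  stim <- make_stimuli(8, 2, 2, 3, 1)
  sch <- make_schedule(stim, phase = "test") # 4 events x 250 ms
  spikes <- data.frame(
    time_ms = seq(0, 225, by = 25), layer = 2, pop = "E",
    neuron = 1, event = 1
  ) # 10 spikes in event 1
  r <- rates_from_spikes(spikes, sch, n_cells = 3)
  expect_equal(r[1, 1, 1], 40) # 10 spikes / 0.25 s
  expect_equal(sum(r[2, , ]), 0) # silent cell
  expect_equal(dim(r), c(3, 2, 2))

  expect_error(rates_from_spikes(spikes, sch[-2, ], 3), "complete")
})

test_that("a perfectly invariant, selective cell attains 1 bit; a constant cell 0", {
  # cell 1: rate 20 for every transform of stimulus 1, 5 for stimulus 2
  r <- array(0, c(3, 2, 4))
  r[1, 1, ] <- 20
  r[1, 2, ] <- 5
  r[2, , ] <- 13 # constant responder
  r[3, , ] <- 0  # silent
  sci <- single_cell_info(make_rate_table(r), n_bins = 4)
  expect_equal(sci$max_bits[1], 1)
  expect_equal(sci$max_bits[2], 0)
  expect_equal(sci$max_bits[3], 0)
})

test_that("single-cell information equals the exhaustive enumeration oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n_t <- sample(3:6, 1)
    r <- array(sample(0:8, 2 * 2 * n_t, replace = TRUE), c(2, 2, n_t))
    n_bins <- sample(2:5, 1)
    sci <- single_cell_info(make_rate_table(r), n_bins = n_bins)
    for (cell in 1:2) {
      expect_equal(sci$per_stimulus[cell, ],
                   oracle_cell_info(matrix(r[cell, , ], 2, n_t), n_bins))
    }
  }
  # half-responder from the spec example family: distinct bin for half of
  # stimulus 1's transforms, baseline otherwise
  r <- array(0, c(1, 2, 4))
  r[1, 1, ] <- c(9, 9, 1, 1)
  r[1, 2, ] <- 1
  sci <- single_cell_info(make_rate_table(r), n_bins = 3)
  expect_equal(sci$per_stimulus[1, ],
               oracle_cell_info(matrix(r[1, , ], 2, 4), 3))
})

test_that("information is bounded by log2(N_S) and invariant to relabeling and rate scaling", {
  set.seed(17)
  r <- array(runif(5 * 2 * 4, 0, 50), c(5, 2, 4))
  rt <- make_rate_table(r)
  sci <- single_cell_info(rt)
  expect_true(all(sci$max_bits >= 0 & sci$max_bits <= 1))

  perm_cells <- r[c(3, 1, 5, 2, 4), , , drop = FALSE]
  expect_equal(sort(single_cell_info(make_rate_table(perm_cells))$max_bits),
               sort(sci$max_bits))
  swap_stim <- r[, c(2, 1), , drop = FALSE]
  expect_equal(single_cell_info(make_rate_table(swap_stim))$max_bits,
               sci$max_bits)
  # strictly monotone scaling preserves bin assignment, hence information
  expect_equal(single_cell_info(make_rate_table(r * 2.5))$max_bits,
               sci$max_bits)

  set.seed(4)
  mci <- multi_cell_info(rt, n_iterations = 10)
  expect_true(all(mci$bits >= 0 & mci$bits <= 1 + 1e-12))
})

test_that("two perfectly opposing cells decode both stimuli perfectly (1 bit)", {
  r <- array(0, c(2, 2, 4))
  r[1, 1, ] <- 10 # cell 1 fires only to stimulus 1
  r[2, 2, ] <- 10 # cell 2 fires only to stimulus 2
  set.seed(8)
  mci <- multi_cell_info(make_rate_table(r), n_iterations = 20)
  expect_equal(mci$bits[length(mci$bits)], 1)
  expect_equal(diag(mci$confusion), c(0.5, 0.5))
})

test_that("stimulus-independent responses carry about zero information", {
  set.seed(23)
  # every response drawn iid from the same distribution regardless of stimulus
  r <- array(runif(6 * 2 * 8, 0, 30), c(6, 2, 8))
  set.seed(5)
  mci <- multi_cell_info(make_rate_table(r), n_iterations = 30)
  expect_lt(max(mci$bits), 0.2)
})

test_that("decoding pipeline reproduces the hand-computed confusion table", {
  # 3 cells x 2 stimuli x 4 transforms, integer rates, no posterior ties
  set.seed(12)
  r <- array(sample(0:20, 24, replace = TRUE), c(3, 2, 4))
  rt <- make_rate_table(r)
  sd_floor <- 1e-3 * max(r)

  # oracle: explicit leave-one-transform-out Gaussian-Bayes argmax decoding
  # with the full 3-cell ensemble
  p <- oracle_confusion(r, sd_floor)
  oracle_bits <- confusion_bits(p)

  set.seed(3)
  mci <- multi_cell_info(rt, ensemble_max = 3, n_iterations = 5,
                         n_per_stimulus = 3)
  expect_true(all(1:3 %in% mci$ensemble))
  expect_equal(mci$confusion, p)
  expect_equal(mci$bits[3], oracle_bits)
})

test_that("ensembles of independently selective cells gain information with size", {
  set.seed(19)
  n_cells <- 6
  r <- array(0, c(n_cells, 2, 5))
  for (cell in 1:n_cells) {
    pref <- 1 + (cell %% 2)
    r[cell, pref, ] <- rnorm(5, 20, 4)
    r[cell, 3 - pref, ] <- rnorm(5, 8, 4)
  }
  r[r < 0] <- 0
  set.seed(6)
  mci <- multi_cell_info(make_rate_table(r), ensemble_max = 6,
                         n_iterations = 50, n_per_stimulus = 3)
  expect_true(all(diff(mci$bits) > -0.08)) # non-decreasing up to MC error
  k <- length(mci$bits)
  expect_gte(mci$bits[k], mci$bits[1] - 1e-9)
})

test_that("volley counting recovers synchronized population waves", {
  # five volleys of 40 neurons at 20 ms spacing, with 0.5 ms within-volley jitter
  set.seed(2)
  times <- unlist(lapply(seq(5, 85, by = 20), function(t0) t0 + runif(40, 0, 0.5)))
  neurons <- rep(1:40, times = 5)
  v <- count_volleys(times, neurons, n_stimulated = 40, window_ms = 100)
  expect_equal(v$n_volleys, 5L)
  expect_equal(v$rate_hz, 50)

  # sparse desynchronized firing recruits too few cells per cluster
  v2 <- count_volleys(seq(1, 99, by = 7), rep(1:5, 3)[1:15],
                      n_stimulated = 40, window_ms = 100)
  expect_equal(v2$n_volleys, 0L)
  expect_equal(count_volleys(numeric(0), integer(0), 40, 100)$n_volleys, 0L)
})
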