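dt <- 0.02

test_that("trace jumps close a fixed fraction of the distance to one", {
  p <- plasticity_params()
  st <- plasticity_state(1, 1)
  st <- step_traces(st, TRUE, FALSE, p, dt)
  expect_equal(st$C, 0.5, tolerance = 1e-6)
  st <- step_traces(st, TRUE, FALSE, p, dt)
  expect_lt(abs(st$C - 0.75), 1e-3) # slight decay between the two steps
  expect_lt(st$C, 1)
  st2 <- plasticity_state(1, 1)
  st2 <- step_traces(st2, FALSE, TRUE, p, dt)
  expect_equal(st2$D, 0.5, tolerance = 1e-6)
})

test_that("trace decay matches the closed-form exponential within 1%", {
  p <- plasticity_params(tau_C_ms = 15, tau_D_ms = 25)
  st <- plasticity_state(1, 1)
  st$C <- 0.5
  st$D <- 0.5
  for (k in seq_len(round(15 / dt))) {
    st <- step_traces(st, FALSE, FALSE, p, dt)
  }
  expect_equal(st$C, 0.5 * exp(-1), tolerance = 0.01)
  expect_equal(st$D, 0.5 * exp(-15 / 25), tolerance = 0.01)
})

test_that("event-driven analytic trajectory is reproduced within Euler error", {
  # pre spikes at 5, 12, 30 ms; exact solution decays exponentially between
  # spikes and jumps by alpha*(1-C) at each spike
  p <- plasticity_params(tau_C_ms = 15)
  spikes_ms <- c(5, 12, 30)
  horizon <- 40
  st <- plasticity_state(1, 1)
  spike_steps <- round(spikes_ms / dt)
  for (k in seq_len(round(horizon / dt))) {
    st <- step_traces(st, k %in% spike_steps, FALSE, p, dt)
  }
  c_exact <- 0
  t_prev <- 0
  for (ts in spikes_ms) {
    c_exact <- c_exact * exp(-(ts - t_prev) / 15)
    c_exact <- c_exact + 0.5 * (1 - c_exact)
    t_prev <- ts
  }
  c_exact <- c_exact * exp(-(horizon - t_prev) / 15)
  expect_equal(st$C, c_exact, tolerance = 0.01)
})

test_that("weight updates follow the multiplicative LTP/LTD rule exactly", {
  p <- plasticity_params()
  st <- plasticity_state(1, 1)
  st$C <- 0.3
  Dg <- matrix(0.5, 1, 1)
  up <- apply_weight_updates(Dg, st, FALSE, TRUE, p)
  expect_equal(up[1, 1], 0.5 + 0.1 * 0.5 * 0.3) # +0.015

  st$D <- 0.4
  down <- apply_weight_updates(Dg, st, TRUE, FALSE, p)
  expect_equal(down[1, 1], 0.5 - 0.1 * 0.5 * 0.4) # -0.020

  # saturation: LTP cannot move Dg = 1, LTD cannot move Dg = 0
  st$C <- 0.9
  expect_equal(apply_weight_updates(matrix(1, 1, 1), st, FALSE, TRUE, p)[1, 1], 1)
  st$D <- 0.9
  expect_equal(apply_weight_updates(matrix(0, 1, 1), st, TRUE, FALSE, p)[1, 1], 0)
})

simulate_pairing <- function(dt_pair_ms, order = c("pre_post", "post_pre"),
                             params = plasticity_params()) {
  # one pre and one post spike separated by dt_pair_ms, starting from rest
  order <- match.arg(order)
  first_ms <- 2
  second_ms <- first_ms + dt_pair_ms
  horizon <- second_ms + 2
  st <- plasticity_state(1, 1)
  Dg <- matrix(0.5, 1, 1)
  for (k in seq_len(round(horizon / dt))) {
    t_ms <- k * dt
    pre <- isTRUE(all.equal(t_ms, if (order == "pre_post") first_ms else second_ms))
    post <- isTRUE(all.equal(t_ms, if (order == "pre_post") second_ms else first_ms))
    st <- step_traces(st, pre, post, params, dt)
    Dg <- apply_weight_updates(Dg, st, pre, post, params)
  }
  Dg[1, 1] - 0.5
}

test_that("causal pre-post pairing potentiates, anti-causal depresses, decaying with the gap", {
  gaps <- c(1, 5, 20, 60)
  ltp <- vapply(gaps, simulate_pairing, numeric(1), order = "pre_post")
  ltd <- vapply(gaps, simulate_pairing, numeric(1), order = "post_pre")
  expect_true(all(ltp > 0))
  expect_true(all(ltd < 0))
  expect_true(all(diff(ltp) < 0))        # exponentially weaker with the gap
  expect_true(all(diff(abs(ltd)) < 0))
  # decay constants: LTP follows tau_C, LTD follows tau_D
  expect_equal(ltp[2] / ltp[1], exp(-(5 - 1) / 15), tolerance = 0.01)
  expect_equal(ltd[2] / ltd[1], exp(-(5 - 1) / 25), tolerance = 0.01)
})

test_that("efficacies never leave [0,1] under random spike trains", {
  set.seed(9)
  p <- plasticity_params(tau_C_ms = 3, tau_D_ms = 5)
  for (rep in 1:5) {
    st <- plasticity_state(4, 3)
    Dg <- matrix(runif(12), 3, 4)
    lo <- Inf
    hi <- -Inf
    trace_lo <- Inf
    trace_hi <- -Inf
    for (k in 1:400) {
      pre <- runif(4) < 0.1
      post <- runif(3) < 0.1
      st <- step_traces(st, pre, post, p, dt)
      Dg <- apply_weight_updates(Dg, st, pre, post, p)
      lo <- min(lo, Dg)
      hi <- max(hi, Dg)
      trace_lo <- min(trace_lo, st$C, st$D)
      trace_hi <- max(trace_hi, st$C, st$D)
    }
    expect_gte(lo, 0)
    expect_lte(hi, 1)
    expect_gte(trace_lo, 0)
    expect_lte(trace_hi, 1)
  }
})

test_that("updates vanish as the learning rate goes to zero", {
  p <- plasticity_params(rho = 1e-12)
  st <- plasticity_state(2, 2)
  st$C[] <- 0.9
  st$D[] <- 0.9
  Dg <- matrix(0.5, 2, 2)
  out <- apply_weight_updates(Dg, st, c(TRUE, TRUE), c(TRUE, TRUE), p)
  expect_lt(max(abs(out - Dg)), 1e-11)
})

test_that("weight histograms are flat before training and concentrated when degenerate", {
  set.seed(2)
  Dg <- matrix(runif(160000), 400, 400)
  h <- weight_histogram(Dg, n_bins = 20)
  expect_equal(sum(h$count), 160000)
  chi <- suppressWarnings(chisq.test(h$count))
  expect_gt(chi$p.value, 0.01)

  h2 <- weight_histogram(matrix(0.5, 10, 10), n_bins = 4)
  expect_equal(sum(h2$count > 0), 1)
  expect_equal(h2$count[3], 100) # 0.5 falls in the [0.5, 0.75) bin
})
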