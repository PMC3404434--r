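exc <- population_params("excitatory")
dt <- 0.02

test_that("resting potential is a fixed point with no input and no noise", {
  st <- layer_state(3, exc)
  for (k in 1:100) st <- step_membrane(st, exc, 0, dt, noise = FALSE)
  expect_equal(st$V_mV, rep(exc$v0_mV, 3))
  expect_false(any(st$spiked))
})

test_that("membrane relaxation matches the closed-form exponential within 0.1%", {
  st <- layer_state(1, exc)
  st$V_mV <- -60
  n <- round(20 / dt)
  for (k in seq_len(n)) st <- step_membrane(st, exc, 0, dt, noise = FALSE)
  v_exact <- exc$v0_mV + (-60 - exc$v0_mV) * exp(-20 / exc$tau_m_ms)
  expect_lt(abs(st$V_mV - v_exact) / abs(v_exact), 0.001)
})

test_that("constant-current firing rate matches the closed-form ISI within 2%", {
  # 1 nA drive: V_inf = V0 + I/g0 = -34 mV, ISI = tau_R + tau_m*ln((Vinf-VH)/(Vinf-Theta))
  v_inf <- exc$v0_mV + 1000 / exc$g0_nS
  expect_equal(v_inf, -34)
  isi <- exc$tau_R_ms + exc$tau_m_ms *
    log((v_inf - exc$vH_mV) / (v_inf - exc$theta_mV))
  expect_equal(isi, 5.8211, tolerance = 1e-4)

  st <- layer_state(1, exc)
  st$I_ext_pA <- 1000
  horizon_ms <- 500
  n_spikes <- 0
  first_spike <- NA
  last_spike <- NA
  for (k in seq_len(round(horizon_ms / dt))) {
    st <- step_membrane(st, exc, 0, dt, noise = FALSE)
    if (st$spiked) {
      n_spikes <- n_spikes + 1
      if (is.na(first_spike)) first_spike <- k * dt
      last_spike <- k * dt
    }
  }
  sim_isi <- (last_spike - first_spike) / (n_spikes - 1)
  expect_lt(abs(sim_isi - isi) / isi, 0.02)
  expect_gt(1000 / sim_isi, 0.98 * 171.8) # ~172 Hz
  expect_lt(1000 / sim_isi, 1.02 * 171.8)
})

test_that("spiking resets to V_H and silences the neuron for ceil(tau_R/dt) steps", {
  st <- layer_state(1, exc)
  st$V_mV <- exc$theta_mV + 1 # force an immediate threshold crossing
  st$I_ext_pA <- 1000
  st <- step_membrane(st, exc, 0, dt, noise = FALSE)
  expect_true(st$spiked)
  expect_equal(st$V_mV, exc$vH_mV)
  n_clamped <- 0
  repeat {
    st <- step_membrane(st, exc, 0, dt, noise = FALSE)
    if (st$V_mV != exc$vH_mV || st$spiked) break
    n_clamped <- n_clamped + 1
    if (n_clamped > 300) break
  }
  expect_equal(n_clamped, ceiling(exc$tau_R_ms / dt))
})

test_that("stationary membrane variance scales with sigma^2 and vanishes without noise", {
  run_var <- function(coeff) {
    p <- population_params("excitatory", sigma_coeff = coeff)
    st <- layer_state(400, p)
    for (k in seq_len(2000)) st <- step_membrane(st, p, 0, dt, noise = TRUE)
    var(st$V_mV)
  }
  set.seed(11)
  v1 <- run_var(0.015)
  v2 <- run_var(0.030)
  expect_gt(v1, 0)
  expect_equal(v2 / v1, 4, tolerance = 0.35) # sigma doubled -> 4x variance
  expect_equal(run_var(0), 0)
})

test_that("synaptic currents follow the conductance-reversal products", {
  # no conductance -> no current
  g0 <- synapse_group("excitatory", "excitatory", matrix(0.5, 2, 1), 1, 2)
  expect_equal(synaptic_current(c(-74, -60), list(g0)), c(0, 0))

  # single excitatory synapse of 1 nS at -74 mV -> 74 pA
  gE <- g0
  gE$g_nS <- matrix(c(1, 0), 2, 1)
  expect_equal(synaptic_current(c(-74, -74), list(gE)), c(74, 0))

  # inhibitory synapse at its reversal potential -> zero current
  gI <- synapse_group("inhibitory", "excitatory", matrix(1, 1, 1), 1, 5)
  gI$g_nS <- matrix(1, 1, 1)
  expect_equal(synaptic_current(-70, list(gI)), 0)
  # ... and negative current above it
  expect_lt(synaptic_current(-55, list(gI)), 0)

  expect_error(synaptic_current(c(-74, -74, -74), list(gE)), "neurons")
})

test_that("conductances decay to the closed form and jump by lambda * Dg", {
  g <- synapse_group("excitatory", "excitatory", matrix(0.5, 1, 1), 5, 2)
  g$g_nS[1, 1] <- 2
  for (k in seq_len(round(2 / dt))) {
    g <- step_conductances(g, FALSE, dt)
  }
  expect_equal(g$g_nS[1, 1], 2 * exp(-1), tolerance = 0.01)

  # one spike arriving at Dg = 0.5 with lambda = 5 nS adds 2.5 nS
  before <- g$g_nS[1, 1]
  g <- step_conductances(g, TRUE, dt)
  expect_equal(g$g_nS[1, 1], before * (1 - dt / 2) + 2.5)

  # Dg = 0: spikes leave the conductance unchanged
  gz <- synapse_group("excitatory", "excitatory", matrix(0, 1, 1), 5, 2)
  gz$g_nS[1, 1] <- 1
  gz <- step_conductances(gz, TRUE, dt)
  expect_equal(gz$g_nS[1, 1], 1 * (1 - dt / 2))

  expect_error(synapse_group("excitatory", "excitatory", matrix(0.5, 1, 1),
                             5, -1), "tau_g")
})

test_that("conductances stay non-negative under random spike trains", {
  set.seed(5)
  g <- synapse_group("excitatory", "excitatory",
                     matrix(runif(6), 2, 3), 5, 2)
  for (k in 1:500) {
    g <- step_conductances(g, runif(3) < 0.05, dt)
    expect_true(all(g$g_nS >= 0))
  }
})

test_that("non-finite membrane state fails loudly with the neuron index", {
  st <- layer_state(3, exc)
  st$V_mV[2] <- NaN
  expect_error(step_membrane(st, exc, 0, dt, noise = FALSE), "neuron 2")
})
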