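# Naive per-synapse reference simulator, used as the independent oracle for
# the fused C++ engine. Every projection keeps a full conductance matrix and
# the presynaptic STDP trace is kept per synapse (a matrix), so the engine's
# aggregation shortcuts (scalar conductance sums, per-presynaptic-neuron C)
# are genuinely exercised. Noise must be off for exact comparison.
reference_run <- function(config, W0, stimset, schedule, learning_on = FALSE) {
  nE <- config$n_exc
  nI <- config$n_inh
  dt <- config$dt_ms
  pl <- config$plasticity
  stopifnot(!config$noise)

  pops <- list(
    l1e = layer_state(nE, config$exc), l1i = layer_state(nI, config$inh),
    l2e = layer_state(nE, config$exc), l2i = layer_state(nI, config$inh)
  )
  ones <- function(np, npre) matrix(1, np, npre)
  grp <- function(src, tgt, Dg, lam, tau, plastic = FALSE) {
    synapse_group(src, tgt, Dg, lam, tau, delay_ms = 0, plastic = plastic)
  }
  groups <- list(
    EI1 = grp("excitatory", "inhibitory", ones(nI, nE), config$g_EI_nS,
              config$tau_EI_ms),
    IE1 = grp("inhibitory", "excitatory", ones(nE, nI), config$g_IE_nS,
              config$tau_IE_ms),
    II1 = grp("inhibitory", "inhibitory", ones(nI, nI), config$g_II_nS,
              config$tau_II_ms),
    FF = grp("excitatory", "excitatory", t(W0), config$lambda_EE_nS,
             config$tau_EE_ms, plastic = TRUE),
    EI2 = grp("excitatory", "inhibitory", ones(nI, nE), config$g_EI_nS,
              config$tau_EI_ms),
    IE2 = grp("inhibitory", "excitatory", ones(nE, nI), config$g_IE_nS,
              config$tau_IE_ms),
    II2 = grp("inhibitory", "inhibitory", ones(nI, nI), config$g_II_nS,
              config$tau_II_ms)
  )
  Cm <- matrix(0, nE, nE) # per-synapse presynaptic trace (post x pre)
  D <- rep(0, nE)
  prev <- list(l1e = logical(nE), l1i = logical(nI),
               l2e = logical(nE), l2i = logical(nI))
  spikes <- list()
  t_step <- 0L

  for (e in seq_len(nrow(schedule))) {
    if (schedule$reset_before[e]) {
      for (nm in names(pops)) {
        pops[[nm]]$V_mV[] <- if (grepl("e$", nm)) config$exc$v0_mV else config$inh$v0_mV
        pops[[nm]]$refractory_ms[] <- 0
      }
      for (nm in names(groups)) groups[[nm]]$g_nS[] <- 0
      Cm[] <- 0
      D[] <- 0
      prev <- lapply(prev, function(x) x & FALSE)
    }
    iext <- rep(0, nE)
    idx <- stimset$transforms[[schedule$stimulus[e]]][[schedule$transform[e]]]
    iext[idx] <- schedule$i_ext_nA[e] * 1000
    pops$l1e$I_ext_pA <- iext
    nsteps <- round(schedule$duration_ms[e] / dt)

    for (s in seq_len(nsteps)) {
      # (1) conductances, fed by the previous step's spikes
      groups$EI1 <- step_conductances(groups$EI1, prev$l1e, dt)
      groups$IE1 <- step_conductances(groups$IE1, prev$l1i, dt)
      groups$II1 <- step_conductances(groups$II1, prev$l1i, dt)
      groups$FF <- step_conductances(groups$FF, prev$l1e, dt)
      groups$EI2 <- step_conductances(groups$EI2, prev$l2e, dt)
      groups$IE2 <- step_conductances(groups$IE2, prev$l2i, dt)
      groups$II2 <- step_conductances(groups$II2, prev$l2i, dt)
      # (2) currents, (3) membranes
      I1e <- synaptic_current(pops$l1e$V_mV, groups["IE1"])
      I1i <- synaptic_current(pops$l1i$V_mV, groups[c("EI1", "II1")])
      I2e <- synaptic_current(pops$l2e$V_mV, groups[c("FF", "IE2")])
      I2i <- synaptic_current(pops$l2i$V_mV, groups[c("EI2", "II2")])
      pops$l1e <- step_membrane(pops$l1e, config$exc, I1e, dt, noise = FALSE)
      pops$l1i <- step_membrane(pops$l1i, config$inh, I1i, dt, noise = FALSE)
      pops$l2e <- step_membrane(pops$l2e, config$exc, I2e, dt, noise = FALSE)
      pops$l2i <- step_membrane(pops$l2i, config$inh, I2i, dt, noise = FALSE)
      now <- list(l1e = pops$l1e$spiked, l1i = pops$l1i$spiked,
                  l2e = pops$l2e$spiked, l2i = pops$l2i$spiked)
      # (4) plasticity: per-synapse trace decay, jumps, then LTP before LTD
      if (learning_on) {
        Cm <- Cm * (1 - dt / pl$tau_C_ms)
        D <- D * (1 - dt / pl$tau_D_ms)
        pre <- which(prev$l1e)
        if (length(pre)) {
          Cm[, pre] <- Cm[, pre] + pl$alpha_C * (1 - Cm[, pre, drop = FALSE])
        }
        post <- which(now$l2e)
        if (length(post)) D[post] <- D[post] + pl$alpha_D * (1 - D[post])
        Dg <- groups$FF$Dg
        if (length(post)) {
          Dg[post, ] <- Dg[post, ] +
            pl$rho * (1 - Dg[post, , drop = FALSE]) * Cm[post, , drop = FALSE]
        }
        if (length(pre)) {
          Dg[, pre] <- Dg[, pre] - pl$rho * Dg[, pre, drop = FALSE] * D
        }
        groups$FF$Dg <- Dg
      }
      for (nm in names(now)) {
        if (any(now[[nm]])) {
          spikes[[length(spikes) + 1]] <- data.frame(
            time_ms = t_step * dt,
            layer = if (nm %in% c("l1e", "l1i")) 1L else 2L,
            pop = if (grepl("e$", nm)) "E" else "I",
            neuron = which(now[[nm]]), event = e
          )
        }
      }
      prev <- now
      t_step <- t_step + 1L
    }
  }
  spk <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(time_ms = numeric(), layer = integer(), pop = character(),
               neuron = integer(), event = integer())
  list(spikes = spk, weights = t(groups$FF$Dg), C = Cm, D = D,
       V_input_exc = pops$l1e$V_mV, V_output_exc = pops$l2e$V_mV)
}

# small noise-free configuration that still produces spikes in both layers
tiny_config <- function(...) {
  network_config(
    n_exc = 8, n_inh = 2, g_IE_nS = 2.5, g_EI_nS = 5, g_II_nS = 5,
    lambda_EE_nS = 40, # few synapses, so a large cap is needed to drive L2
    noise = FALSE, noise_inh = FALSE, ...
  )
}

tiny_stimuli <- function() make_stimuli(8, 2, 2, 3, 1)
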