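#' Create the membrane state of one population
#'
#' @param n number of neurons.
#' @param params [population_params()].
#' @return A `layer_state` list: membrane potentials `V_mV` (at rest),
#'   `refractory_ms` remaining clamp time, `spiked` logical flags for the most
#'   recent step, and injected current `I_ext_pA`.
#' @export
layer_state <- function(n, params) {
  stopifnot(n >= 1, inherits(params, "population_params"))
  structure(
    list(V_mV = rep(params$v0_mV, n),
         refractory_ms = rep(0, n),
         spiked = rep(FALSE, n),
         I_ext_pA = rep(0, n)),
    class = "layer_state"
  )
}

#' Advance membrane potentials by one Forward-Euler step
#'
#' Integrates the conductance-based leaky integrate-and-fire membrane equation
#' `tau_m dV/dt = (V0 - V) + I/g0` for one step of `dt_ms`, with the
#' stochastic term handled by Euler-Maruyama: each non-refractory neuron
#' receives `sigma_mV * sqrt(dt/tau_m) * N(0,1)` per step, so the noise
#' amplitude scales correctly with the membrane time constant. Neurons whose
#' updated potential reaches the threshold `theta_mV` emit a spike, are reset
#' to `vH_mV` and clamped there for the absolute refractory period; refractory
#' neurons do not integrate (and receive no noise).
#'
#' @param state a `layer_state`.
#' @param params [population_params()].
#' @param I_syn_pA per-neuron synaptic current (pA), see [synaptic_current()].
#' @param dt_ms time step (ms).
#' @param noise logical; draw the Gaussian membrane noise (uses the R RNG).
#' @return The updated `layer_state`; `spiked` marks this step's spikes.
#' @export
step_membrane <- function(state, params, I_syn_pA = 0, dt_ms = 0.02,
                          noise = TRUE) {
  n <- length(state$V_mV)
  I_tot <- I_syn_pA + state$I_ext_pA
  if (length(I_tot) == 1) I_tot <- rep(I_tot, n)
  stopifnot(length(I_tot) == n, dt_ms > 0, all(state$refractory_ms >= 0))
  if (any(!is.finite(state$V_mV)) || any(!is.finite(I_tot))) {
    bad <- which(!is.finite(state$V_mV) | !is.finite(I_tot))[1]
    stop(sprintf("non-finite membrane potential or current at neuron %d", bad))
  }

  active <- state$refractory_ms <= 1e-9  # tolerate float residue of dt sums
  V <- state$V_mV
  dV <- (dt_ms / params$tau_m_ms) *
    (params$v0_mV - V[active] + I_tot[active] / params$g0_nS)
  if (noise && params$sigma_mV > 0 && any(active)) {
    dV <- dV + params$sigma_mV * sqrt(dt_ms / params$tau_m_ms) *
      rnorm(sum(active))
  }
  V[active] <- V[active] + dV

  spiked <- active & (V >= params$theta_mV)
  V[spiked] <- params$vH_mV
  refr <- state$refractory_ms
  refr[!active] <- pmax(refr[!active] - dt_ms, 0)
  V[!active] <- params$vH_mV
  refr[spiked] <- params$tau_R_ms

  state$V_mV <- V
  state$refractory_ms <- refr
  state$spiked <- spiked
  state
}

#' Create one synapse group (projection)
#'
#' A projection holds per-synapse conductances `g_nS` and normalized
#' efficacies `Dg` (both `n_post x n_pre` matrices), the conductance scaling
#' constant `lambda_nS` (so the per-spike conductance increment at synapse
#' `ij` is `lambda_nS * Dg[i, j]`), the decay time constant `tau_g_ms`, a
#' per-projection conduction delay and a plasticity flag.
#'
#' @param source_class,target_class `"excitatory"` or `"inhibitory"`; the
#'   source class selects the reversal potential used in [synaptic_current()].
#' @param Dg efficacy matrix (`n_post x n_pre`), elementwise in `[0, 1]`.
#' @param lambda_nS conductance scaling constant (nS).
#' @param tau_g_ms conductance decay time constant (ms).
#' @param delay_ms conduction delay (ms), uniform within the projection.
#' @param plastic logical.
#' @return A `synapse_group` with `g_nS` initialized to zero.
#' @export
synapse_group <- function(source_class, target_class, Dg, lambda_nS,
                          tau_g_ms, delay_ms = 0, plastic = FALSE) {
  source_class <- match.arg(source_class, c("excitatory", "inhibitory"))
  target_class <- match.arg(target_class, c("excitatory", "inhibitory"))
  Dg <- as.matrix(Dg)
  if (tau_g_ms <= 0) stop("tau_g_ms must be positive")
  stopifnot(all(Dg >= 0), all(Dg <= 1), lambda_nS >= 0, delay_ms >= 0)
  structure(
    list(source_class = source_class, target_class = target_class,
         g_nS = matrix(0, nrow(Dg), ncol(Dg)), Dg = Dg,
         lambda_nS = lambda_nS, tau_g_ms = tau_g_ms,
         delay_ms = delay_ms, plastic = isTRUE(plastic)),
    class = "synapse_group"
  )
}

#' Total synaptic current onto a layer
#'
#' Evaluates `I_i = sum_gamma sum_j g_ij * (vhat_gamma - V_i)`: every synapse
#' drives its postsynaptic neuron toward the reversal potential of its source
#' class, so inhibitory synapses contribute negative current whenever the
#' membrane is above the inhibitory reversal potential.
#'
#' @param V_mV postsynaptic membrane potentials (mV).
#' @param groups list of `synapse_group`s targeting this layer.
#' @param vhatE_mV,vhatI_mV reversal potentials (mV).
#' @return Per-neuron current (pA).
#' @export
synaptic_current <- function(V_mV, groups, vhatE_mV = 0, vhatI_mV = -70) {
  n <- length(V_mV)
  I <- rep(0, n)
  for (grp in groups) {
    if (nrow(grp$g_nS) != n) {
      stop(sprintf(
        "synapse group has %d postsynaptic rows but layer has %d neurons",
        nrow(grp$g_nS), n
      ))
    }
    vhat <- if (grp$source_class == "excitatory") vhatE_mV else vhatI_mV
    I <- I + rowSums(grp$g_nS) * (vhat - V_mV)
  }
  I
}

#' Advance a projection's conductances by one Euler step
#'
#' Conductances decay as `dg/dt = -g/tau_g`; each delayed presynaptic spike
#' instantaneously increments its synapses by `lambda_nS * Dg[, j]` (the
#' discrete delta pulse of the Euler scheme absorbs the `1/dt`, so the
#' increment is exactly `lambda * Dg`).
#'
#' @param group a `synapse_group`.
#' @param pre_spikes logical vector over presynaptic neurons: spikes arriving
#'   this step (i.e. emitted `delay` ago).
#' @param dt_ms time step (ms).
#' @return The updated `synapse_group`.
#' @export
step_conductances <- function(group, pre_spikes, dt_ms = 0.02) {
  stopifnot(dt_ms > 0, length(pre_spikes) == ncol(group$g_nS))
  g <- group$g_nS * (1 - dt_ms / group$tau_g_ms)
  idx <- which(pre_spikes)
  if (length(idx)) {
    g[, idx] <- g[, idx] + group$lambda_nS * group$Dg[, idx, drop = FALSE]
  }
  group$g_nS <- g
  group
}
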