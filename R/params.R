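#' Cellular parameters for one neuron class
#'
#' Constructs the constants of a conductance-based leaky integrate-and-fire
#' population. Defaults are the standard excitatory/inhibitory pyramidal and
#' interneuron values used throughout the simulations: membrane capacitance
#' `c_m_pF`, leak conductance `g0_nS` (so the membrane time constant is
#' `tau_m = c_m/g0`), resting potential `v0_mV`, firing threshold `theta_mV`,
#' after-spike hyperpolarization `vH_mV`, excitatory/inhibitory synaptic
#' reversal potentials (`vhatE_mV = 0`, `vhatI_mV = -70`), absolute refractory
#' period `tau_R_ms`, and the membrane-noise amplitude
#' `sigma_mV = sigma_coeff * (theta - vH)`.
#'
#' Units: mV for potentials, nS for conductances, pF for capacitance, ms for
#' times. Currents are carried in pA so that `g (nS) * V (mV) = I (pA)` and
#' `I (pA) / g0 (nS) = V (mV)`.
#'
#' @param class_label `"excitatory"` or `"inhibitory"`.
#' @param c_m_pF somatic capacitance (pF).
#' @param g0_nS somatic leak conductance (nS).
#' @param v0_mV resting potential (mV).
#' @param theta_mV firing threshold (mV).
#' @param vH_mV after-spike hyperpolarization potential (mV).
#' @param vhatE_mV,vhatI_mV reversal potentials of excitatory and inhibitory
#'   synapses onto this population (mV).
#' @param tau_R_ms absolute refractory period (ms).
#' @param sigma_coeff dimensionless noise coefficient; the Gaussian membrane
#'   noise has standard deviation `sigma_coeff * (theta_mV - vH_mV)` mV.
#' @return An object of class `population_params` (a validated list, with the
#'   derived fields `tau_m_ms` and `sigma_mV`).
#' @examples
#' population_params("excitatory")$tau_m_ms  # 20 ms
#' @export
population_params <- function(class_label = c("excitatory", "inhibitory"),
                              c_m_pF = NULL, g0_nS = NULL, v0_mV = NULL,
                              theta_mV = -53, vH_mV = NULL,
                              vhatE_mV = 0, vhatI_mV = -70,
                              tau_R_ms = 2, sigma_coeff = 0.015) {
  class_label <- match.arg(class_label)
  defaults <- if (class_label == "excitatory") {
    list(c_m_pF = 500, g0_nS = 25, v0_mV = -74, vH_mV = -57)
  } else {
    list(c_m_pF = 214, g0_nS = 18, v0_mV = -82, vH_mV = -58)
  }
  c_m_pF <- c_m_pF %||% defaults$c_m_pF
  g0_nS <- g0_nS %||% defaults$g0_nS
  v0_mV <- v0_mV %||% defaults$v0_mV
  vH_mV <- vH_mV %||% defaults$vH_mV

  p <- list(
    class_label = class_label,
    c_m_pF = c_m_pF, g0_nS = g0_nS,
    tau_m_ms = c_m_pF / g0_nS,
    v0_mV = v0_mV, theta_mV = theta_mV, vH_mV = vH_mV,
    vhatE_mV = vhatE_mV, vhatI_mV = vhatI_mV,
    tau_R_ms = tau_R_ms,
    sigma_coeff = sigma_coeff,
    sigma_mV = sigma_coeff * (theta_mV - vH_mV)
  )
  class(p) <- "population_params"
  validate_population_params(p)
  p
}

validate_population_params <- function(p) {
  stopifnot(
    p$c_m_pF > 0, p$g0_nS > 0, p$tau_R_ms > 0,
    p$theta_mV > p$vH_mV, p$theta_mV > p$v0_mV,
    p$sigma_coeff >= 0
  )
  invisible(p)
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "<population_params: %s>\n  C_m = %g pF, g_0 = %g nS (tau_m = %.3g ms)\n  V_0 = %g mV, Theta = %g mV, V_H = %g mV\n  reversal E/I = %g/%g mV, tau_R = %g ms, sigma = %.4g mV\n",
    x$class_label, x$c_m_pF, x$g0_nS, x$tau_m_ms, x$v0_mV, x$theta_mV,
    x$vH_mV, x$vhatE_mV, x$vhatI_mV, x$tau_R_ms, x$sigma_mV
  ))
  invisible(x)
}

#' STDP parameters for the plastic feed-forward projection
#'
#' The multiplicative STDP rule tracks a presynaptic trace `C` (interpreted as
#' neurotransmitter concentration, incremented by `alpha_C * (1 - C)` at each
#' delayed presynaptic spike, decaying with `tau_C_ms`) and a postsynaptic
#' trace `D` (proportion of unblocked NMDA receptors, incremented by
#' `alpha_D * (1 - D)` at each postsynaptic spike, decaying with `tau_D_ms`).
#' At a postsynaptic spike the normalized efficacy potentiates by
#' `rho * (1 - Dg) * C` (LTP); at a delayed presynaptic spike it depresses by
#' `rho * Dg * D` (LTD). Both traces and `Dg` stay in `[0, 1]` by construction
#' when `0 <= alpha < 1`.
#'
#' @param alpha_C,alpha_D trace increment fractions in `[0, 1)`.
#' @param tau_C_ms,tau_D_ms trace decay time constants (ms); defaults 15/25 ms,
#'   with 3/5 and 75/125 used for the temporal-specificity manipulations.
#' @param rho dimensionless learning rate (the discrete-time `dt/tau_dg`).
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha_C = 0.5, alpha_D = 0.5,
                              tau_C_ms = 15, tau_D_ms = 25, rho = 0.1) {
  stopifnot(
    alpha_C >= 0, alpha_C < 1, alpha_D >= 0, alpha_D < 1,
    tau_C_ms > 0, tau_D_ms > 0, rho > 0
  )
  structure(
    list(alpha_C = alpha_C, alpha_D = alpha_D,
         tau_C_ms = tau_C_ms, tau_D_ms = tau_D_ms, rho = rho),
    class = "plasticity_params"
  )
}

#' Network configuration
#'
#' Assembles the full description of the two-layer architecture: an input and
#' an output layer, each with `n_exc` excitatory cells fully reciprocally
#' connected to `n_inh` inhibitory interneurons (non-plastic), plus one plastic
#' all-to-all feed-forward excitatory projection from input to output layer.
#'
#' Non-plastic synapses are specified directly by their per-spike conductance
#' increments (the product `lambda * Delta_g` of the scaling constant and the
#' fixed efficacy): `g_EI_nS` and `g_II_nS` default to 5 nS and the
#' inhibitory-to-excitatory strength `g_IE_nS` to 2.5 nS (swept down to 0.5 nS
#' in the inhibition experiments). The plastic projection has per-synapse
#' efficacies `Dg` in `[0, 1]` scaled by `lambda_EE_nS`, the conductance cap:
#' 4 nS in the continuous-transformation regime, 1.25 nS in the trace regime.
#'
#' `tau_EE_ms` is the feed-forward synaptic conductance time constant: 2 ms
#' supports learning through spatial overlap (CT), 150 ms leaves a decaying
#' conductance "trace" that bridges temporally adjacent transforms.
#'
#' `scale` shrinks the network proportionally (cell counts multiplied by
#' `scale`, all synaptic increments divided by `scale`) so that the summed
#' synaptic drive per neuron is preserved; used for reduced-size replications.
#'
#' @param n_exc,n_inh excitatory/inhibitory cells per layer (before scaling).
#' @param dt_ms Forward-Euler time step (ms).
#' @param exc,inh [population_params()] for the two classes.
#' @param tau_EE_ms,tau_IE_ms,tau_EI_ms,tau_II_ms synaptic conductance decay
#'   time constants (ms) per projection class.
#' @param g_IE_nS,g_EI_nS,g_II_nS per-spike conductance increments of the
#'   non-plastic projections (nS, already `lambda * Delta_g`).
#' @param lambda_EE_nS conductance scale (cap) of the plastic projection (nS).
#' @param plasticity [plasticity_params()].
#' @param delay_ms named numeric vector of per-projection conduction delays
#'   (ms) with names `EE`, `EI`, `IE`, `II`; a nominal delay of 0 is realized
#'   as a single-step (one `dt_ms`) pipeline.
#' @param noise logical; inject membrane noise into excitatory cells.
#' @param noise_inh logical; also inject noise into inhibitory cells.
#' @param scale proportional scaling factor in `(0, 1]`.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_exc = 400, n_inh = 100, dt_ms = 0.02,
                           exc = population_params("excitatory"),
                           inh = population_params("inhibitory"),
                           tau_EE_ms = 2, tau_IE_ms = 5,
                           tau_EI_ms = 2, tau_II_ms = 5,
                           g_IE_nS = 2.5, g_EI_nS = 5, g_II_nS = 5,
                           lambda_EE_nS = 4,
                           plasticity = plasticity_params(),
                           delay_ms = c(EE = 0, EI = 0, IE = 0, II = 0),
                           noise = TRUE, noise_inh = TRUE,
                           scale = 1) {
  stopifnot(
    dt_ms > 0, scale > 0, scale <= 1,
    tau_EE_ms > 0, tau_IE_ms > 0, tau_EI_ms > 0, tau_II_ms > 0,
    g_IE_nS >= 0, g_EI_nS >= 0, g_II_nS >= 0, lambda_EE_nS >= 0,
    inherits(exc, "population_params"), inherits(inh, "population_params"),
    inherits(plasticity, "plasticity_params"),
    all(c("EE", "EI", "IE", "II") %in% names(delay_ms)),
    all(delay_ms >= 0)
  )
  cfg <- list(
    n_exc = as.integer(round(n_exc * scale)),
    n_inh = as.integer(round(n_inh * scale)),
    dt_ms = dt_ms, exc = exc, inh = inh,
    tau_EE_ms = tau_EE_ms, tau_IE_ms = tau_IE_ms,
    tau_EI_ms = tau_EI_ms, tau_II_ms = tau_II_ms,
    g_IE_nS = g_IE_nS / scale, g_EI_nS = g_EI_nS / scale,
    g_II_nS = g_II_nS / scale,
    lambda_EE_nS = lambda_EE_nS / scale,
    plasticity = plasticity,
    delay_ms = delay_ms[c("EE", "EI", "IE", "II")],
    noise = isTRUE(noise), noise_inh = isTRUE(noise_inh),
    scale = scale
  )
  stopifnot(cfg$n_exc >= 1, cfg$n_inh >= 1)
  class(cfg) <- "network_config"
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config: 2 layers, %d E + %d I cells each (scale %.3g)>\n  tau_g (EE/IE/EI/II) = %g/%g/%g/%g ms\n  increments: g_IE = %.3g, g_EI = %.3g, g_II = %.3g nS; plastic cap lambda_EE = %.3g nS\n  STDP: alpha_C/D = %g/%g, tau_C/D = %g/%g ms, rho = %g\n  dt = %g ms, noise %s\n",
    x$n_exc, x$n_inh, x$scale,
    x$tau_EE_ms, x$tau_IE_ms, x$tau_EI_ms, x$tau_II_ms,
    x$g_IE_nS, x$g_EI_nS, x$g_II_nS, x$lambda_EE_nS,
    x$plasticity$alpha_C, x$plasticity$alpha_D,
    x$plasticity$tau_C_ms, x$plasticity$tau_D_ms, x$plasticity$rho,
    x$dt_ms, if (x$noise) "on" else "off"
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
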