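#' Write / read a network configuration as YAML
#'
#' The file has one section per population (`excitatory`, `inhibitory`) with
#' keys `c_m_pF`, `g0_nS`, `tau_m_ms`, `v0_mV`, `theta_mV`, `vH_mV`,
#' `tau_R_ms`, and one per projection with `tau_g_ms`, conductance strengths
#' and `delay_ms`. The round trip is lossless for all simulated quantities.
#'
#' @param config a [network_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [network_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "network_config"))
  pop <- function(p) {
    list(c_m_pF = p$c_m_pF, g0_nS = p$g0_nS, tau_m_ms = p$tau_m_ms,
         v0_mV = p$v0_mV, theta_mV = p$theta_mV, vH_mV = p$vH_mV,
         vhatE_mV = p$vhatE_mV, vhatI_mV = p$vhatI_mV,
         tau_R_ms = p$tau_R_ms, sigma_coeff = p$sigma_coeff)
  }
  obj <- list(
    network = list(n_exc = config$n_exc, n_inh = config$n_inh,
                   dt_ms = config$dt_ms, scale = config$scale,
                   noise = config$noise, noise_inh = config$noise_inh),
    excitatory = pop(config$exc),
    inhibitory = pop(config$inh),
    projections = list(
      EE = list(tau_g_ms = config$tau_EE_ms,
                lambda_nS = config$lambda_EE_nS,
                delay_ms = unname(config$delay_ms[["EE"]]), plastic = TRUE),
      EI = list(tau_g_ms = config$tau_EI_ms, g_nS = config$g_EI_nS,
                delay_ms = unname(config$delay_ms[["EI"]]), plastic = FALSE),
      IE = list(tau_g_ms = config$tau_IE_ms, g_nS = config$g_IE_nS,
                delay_ms = unname(config$delay_ms[["IE"]]), plastic = FALSE),
      II = list(tau_g_ms = config$tau_II_ms, g_nS = config$g_II_nS,
                delay_ms = unname(config$delay_ms[["II"]]), plastic = FALSE)
    ),
    plasticity = unclass(config$plasticity)
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pop <- function(l, label) {
    population_params(label, c_m_pF = l$c_m_pF, g0_nS = l$g0_nS,
                      v0_mV = l$v0_mV, theta_mV = l$theta_mV,
                      vH_mV = l$vH_mV, vhatE_mV = l$vhatE_mV,
                      vhatI_mV = l$vhatI_mV, tau_R_ms = l$tau_R_ms,
                      sigma_coeff = l$sigma_coeff)
  }
  pr <- obj$projections
  pl <- obj$plasticity
  # increments are stored post-scaling; construct at scale 1 and restore
  cfg <- network_config(
    n_exc = obj$network$n_exc, n_inh = obj$network$n_inh,
    dt_ms = obj$network$dt_ms,
    exc = pop(obj$excitatory, "excitatory"),
    inh = pop(obj$inhibitory, "inhibitory"),
    tau_EE_ms = pr$EE$tau_g_ms, tau_IE_ms = pr$IE$tau_g_ms,
    tau_EI_ms = pr$EI$tau_g_ms, tau_II_ms = pr$II$tau_g_ms,
    g_IE_nS = pr$IE$g_nS, g_EI_nS = pr$EI$g_nS, g_II_nS = pr$II$g_nS,
    lambda_EE_nS = pr$EE$lambda_nS,
    plasticity = plasticity_params(pl$alpha_C, pl$alpha_D,
                                   pl$tau_C_ms, pl$tau_D_ms, pl$rho),
    delay_ms = c(EE = pr$EE$delay_ms, EI = pr$EI$delay_ms,
                 IE = pr$IE$delay_ms, II = pr$II$delay_ms),
    noise = obj$network$noise, noise_inh = obj$network$noise_inh,
    scale = 1
  )
  cfg$n_exc <- as.integer(obj$network$n_exc)
  cfg$n_inh <- as.integer(obj$network$n_inh)
  cfg$scale <- obj$network$scale
  cfg
}

#' Export spike events as delimited text
#'
#' Writes `time_ms, layer, pop, neuron, event_id` (tab-separated).
#'
#' @param spikes spike data.frame from [run_network()].
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  out <- data.frame(time_ms = spikes$time_ms, layer = spikes$layer,
                    pop = as.character(spikes$pop), neuron = spikes$neuron,
                    event_id = spikes$event)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a presentation schedule as delimited text
#'
#' @param schedule a [make_schedule()] data.frame.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Save / load a simulation snapshot
#'
#' Persists the network state (configuration, plastic weight matrix) together
#' with the RNG state so a run can be resumed or audited. Uses R's native
#' serialization.
#'
#' @param state a `network_state`.
#' @param path file path.
#' @export
save_snapshot <- function(state, path) {
  stopifnot(inherits(state, "network_state"))
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  saveRDS(list(state = state, rng_state = rng, saved_at = Sys.time()), path)
  invisible(path)
}

#' @rdname save_snapshot
#' @param restore_rng logical; restore the saved RNG state.
#' @export
load_snapshot <- function(path, restore_rng = FALSE) {
  snap <- readRDS(path)
  if (restore_rng && !is.null(snap$rng_state)) {
    assign(".Random.seed", snap$rng_state, envir = globalenv())
  }
  snap$state
}
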