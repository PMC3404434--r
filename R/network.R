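#' Build the two-layer network state
#'
#' Initializes both layers at their resting potentials and draws the plastic
#' feed-forward efficacies independently from Uniform(0, 1) (the flat initial
#' weight distribution); call `set.seed()` beforehand for reproducibility.
#' Non-plastic efficacies are fixed constants held in the configuration.
#'
#' @param config a [network_config()].
#' @return A `network_state`: the configuration plus the `n_pre x n_post`
#'   plastic weight matrix `weights` (rows: input-layer excitatory cells,
#'   columns: output-layer excitatory cells).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  W <- matrix(runif(config$n_exc * config$n_exc), config$n_exc, config$n_exc)
  structure(list(config = config, weights = W), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state: %d x %d plastic synapses, mean efficacy %.3f>\n",
    nrow(x$weights), ncol(x$weights), mean(x$weights)
  ))
  print(x$config)
  invisible(x)
}

engine_args <- function(config) {
  dl <- config$delay_ms
  pl <- config$plasticity
  list(
    n_exc = config$n_exc, n_inh = config$n_inh, dt_ms = config$dt_ms,
    exc = unclass(config$exc), inh = unclass(config$inh),
    vhatE_mV = config$exc$vhatE_mV, vhatI_mV = config$exc$vhatI_mV,
    tau_EE_ms = config$tau_EE_ms, tau_IE_ms = config$tau_IE_ms,
    tau_EI_ms = config$tau_EI_ms, tau_II_ms = config$tau_II_ms,
    g_EI_nS = config$g_EI_nS, g_IE_nS = config$g_IE_nS,
    g_II_nS = config$g_II_nS, lambda_EE_nS = config$lambda_EE_nS,
    delay_steps_EE = as.integer(max(1, round(dl[["EE"]] / config$dt_ms))),
    delay_steps_EI = as.integer(max(1, round(dl[["EI"]] / config$dt_ms))),
    delay_steps_IE = as.integer(max(1, round(dl[["IE"]] / config$dt_ms))),
    delay_steps_II = as.integer(max(1, round(dl[["II"]] / config$dt_ms))),
    alpha_C = pl$alpha_C, alpha_D = pl$alpha_D,
    tau_C_ms = pl$tau_C_ms, tau_D_ms = pl$tau_D_ms, rho = pl$rho
  )
}

#' Run the network through a presentation schedule
#'
#' Steps the whole network with Forward-Euler at `dt_ms` through every event
#' of the schedule: the cue current is injected into the active transform's
#' input neurons for the event's duration, conductances/membranes advance in
#' both layers, and (when `learning_on`) the STDP traces and weight updates
#' are applied at spike events. Events marked `reset_before` first return the
#' network to its resting state (membrane potentials to `V_0`, synaptic
#' conductances and STDP traces to zero; efficacies are untouched).
#'
#' Within each step the update order is: (1) conductances advance using
#' spikes delayed by the projection's conduction delay, (2) synaptic currents
#' are computed, (3) membranes advance and spikes are detected, (4) STDP
#' trace jumps, then weight updates. A nominal 0 ms delay is realized as a
#' one-step pipeline.
#'
#' @param state a `network_state` from [build_network()].
#' @param stimset the [make_stimuli()] set the schedule indexes into.
#' @param schedule a [make_schedule()] data.frame.
#' @param learning_on logical; when `FALSE` the efficacies are bit-identical
#'   before and after the run.
#' @param record character subset of `c("input", "output", "inhibitory")`:
#'   which populations' spikes to keep.
#' @return A list: `spikes` (data.frame `time_ms`, `layer`, `pop`, `neuron`,
#'   `event`), the updated `state`, and the `schedule`.
#' @export
run_network <- function(state, stimset, schedule, learning_on = FALSE,
                        record = c("output")) {
  stopifnot(inherits(state, "network_state"),
            inherits(stimset, "stimulus_set"),
            nrow(schedule) >= 1)
  config <- state$config
  if (stimset$n_input != config$n_exc) {
    stop("stimulus set was built for a different input-layer size")
  }
  record <- match.arg(record, c("input", "output", "inhibitory", "none"),
                      several.ok = TRUE)
  active <- lapply(seq_len(nrow(schedule)), function(e) {
    idx <- stimset$transforms[[schedule$stimulus[e]]][[schedule$transform[e]]]
    as.integer(idx - 1L)
  })
  sched_cpp <- list(
    duration_steps = as.integer(round(schedule$duration_ms / config$dt_ms)),
    i_ext_pA = schedule$i_ext_nA * 1000,
    reset_before = as.logical(schedule$reset_before),
    active = active
  )
  out <- engine_run(
    engine_args(config), state$weights, sched_cpp,
    learning_on = isTRUE(learning_on),
    noise = config$noise, noise_inh = config$noise_inh,
    record_input = "input" %in% record,
    record_output = "output" %in% record,
    record_inh = "inhibitory" %in% record
  )
  spikes <- data.frame(
    time_ms = out$time_ms, layer = out$layer,
    pop = factor(c("E", "I")[out$pop + 1L], levels = c("E", "I")),
    neuron = out$neuron, event = out$event
  )
  state$weights <- out$weights
  list(spikes = spikes, state = state, schedule = schedule)
}
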