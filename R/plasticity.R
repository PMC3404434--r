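#' Create STDP trace state for a plastic projection
#'
#' `C` is the presynaptic trace (one value per presynaptic neuron: with a
#' uniform per-projection conduction delay the per-synapse trace of Eq-style
#' formulations collapses to a function of the presynaptic spike train alone)
#' and `D` the postsynaptic trace (one value per postsynaptic neuron; it has
#' no conduction delay because the soma is taken to be arbitrarily close to
#' the receiving synapses).
#'
#' @param n_pre,n_post presynaptic/postsynaptic population sizes.
#' @return A `plasticity_state` list with `C` and `D` at zero.
#' @export
plasticity_state <- function(n_pre, n_post) {
  structure(list(C = rep(0, n_pre), D = rep(0, n_post)),
            class = "plasticity_state")
}

#' Advance the STDP traces by one Euler step
#'
#' `C` decays with `tau_C` and jumps by `alpha_C * (1 - C)` at each *delayed*
#' presynaptic spike; `D` decays with `tau_D` and jumps by `alpha_D * (1 - D)`
#' at each (undelayed) postsynaptic spike. Both remain in `[0, 1]` whenever
#' `0 <= alpha < 1`: each jump closes a fixed fraction of the distance to 1.
#'
#' @param state a `plasticity_state`.
#' @param pre_spikes_delayed logical vector over presynaptic neurons.
#' @param post_spikes logical vector over postsynaptic neurons.
#' @param params [plasticity_params()].
#' @param dt_ms time step (ms).
#' @return The updated `plasticity_state`.
#' @export
step_traces <- function(state, pre_spikes_delayed, post_spikes, params,
                        dt_ms = 0.02) {
  stopifnot(dt_ms > 0,
            length(pre_spikes_delayed) == length(state$C),
            length(post_spikes) == length(state$D))
  C <- state$C * (1 - dt_ms / params$tau_C_ms)
  D <- state$D * (1 - dt_ms / params$tau_D_ms)
  C[pre_spikes_delayed] <- C[pre_spikes_delayed] +
    params$alpha_C * (1 - C[pre_spikes_delayed])
  D[post_spikes] <- D[post_spikes] +
    params$alpha_D * (1 - D[post_spikes])
  state$C <- C
  state$D <- D
  state
}

#' Apply multiplicative STDP weight updates at spike events
#'
#' At each postsynaptic spike `i`, all its afferent efficacies potentiate:
#' `Dg[i, ] += rho * (1 - Dg[i, ]) * C` (LTP, gated by recent presynaptic
#' activity). At each delayed presynaptic spike `j`, all its efferent
#' efficacies depress: `Dg[, j] -= rho * Dg[, j] * D` (LTD, gated by recent
#' postsynaptic activity). The multiplicative prefactors keep `Dg` in
#' `[0, 1]` for any spike train. Trace jumps are applied *before* weight
#' updates within a step (see [step_traces()]), and LTP before LTD when both
#' occur in the same step.
#'
#' @param Dg efficacy matrix (`n_post x n_pre`), elementwise in `[0, 1]`.
#' @param state a `plasticity_state` (traces *after* this step's jumps).
#' @param pre_spikes_delayed,post_spikes logical spike vectors.
#' @param params [plasticity_params()].
#' @return The updated efficacy matrix.
#' @export
apply_weight_updates <- function(Dg, state, pre_spikes_delayed, post_spikes,
                                 params) {
  stopifnot(nrow(Dg) == length(state$D), ncol(Dg) == length(state$C))
  post_idx <- which(post_spikes)
  if (length(post_idx)) {
    Dg[post_idx, ] <- Dg[post_idx, ] +
      params$rho * (1 - Dg[post_idx, ]) *
        matrix(state$C, length(post_idx), ncol(Dg), byrow = TRUE)
  }
  pre_idx <- which(pre_spikes_delayed)
  if (length(pre_idx)) {
    Dg[, pre_idx] <- Dg[, pre_idx] -
      params$rho * Dg[, pre_idx, drop = FALSE] * state$D
  }
  Dg
}

#' Histogram of synaptic efficacies
#'
#' Counts the plastic efficacies over equal-width bins on `[0, 1]`. Training
#' reshapes the initially flat (uniform) distribution into a peaked one; the
#' sharper the temporal specificity of the learning, the more mass ends up in
#' the upper bins.
#'
#' @param Dg efficacy matrix or vector with values in `[0, 1]`.
#' @param n_bins number of equal-width bins (>= 2).
#' @return A data.frame with columns `bin_left`, `bin_right`, `count`;
#'   counts sum to `length(Dg)`.
#' @export
weight_histogram <- function(Dg, n_bins = 20) {
  stopifnot(n_bins >= 2, all(Dg >= 0), all(Dg <= 1))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(as.numeric(Dg), breaks,
                                       rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  data.frame(bin_left = breaks[-(n_bins + 1)], bin_right = breaks[-1],
             count = counts)
}
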