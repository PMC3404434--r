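#' Firing-rate table from test-phase spikes
#'
#' Bins each output cell's spikes by presentation event and divides by the
#' event duration, giving the rate (spikes/s) of every cell for every
#' transform of every stimulus.
#'
#' @param spikes spike data.frame from [run_network()] (output-layer
#'   excitatory spikes are used).
#' @param schedule the test [make_schedule()] the spikes were recorded under;
#'   must contain every `(stimulus, transform)` pair exactly once.
#' @param n_cells number of output-layer excitatory cells.
#' @return A `rate_table`: numeric array `cell x stimulus x transform`.
#' @export
rates_from_spikes <- function(spikes, schedule, n_cells) {
  stopifnot(n_cells >= 1)
  grid <- table(schedule$stimulus, schedule$transform)
  if (any(grid != 1)) {
    stop("schedule is not a complete test grid: every (stimulus, transform) pair must appear exactly once")
  }
  n_s <- max(schedule$stimulus)
  n_t <- max(schedule$transform)
  rate <- array(0, dim = c(n_cells, n_s, n_t),
                dimnames = list(cell = NULL, stimulus = NULL, transform = NULL))
  sp <- spikes[spikes$layer == 2 & spikes$pop == "E", ]
  counts <- table(factor(sp$neuron, levels = seq_len(n_cells)),
                  factor(sp$event, levels = schedule$event))
  for (e in seq_len(nrow(schedule))) {
    rate[, schedule$stimulus[e], schedule$transform[e]] <-
      counts[, e] / (schedule$duration_ms[e] / 1000)
  }
  class(rate) <- c("rate_table", class(rate))
  rate
}

#' Stimulus-specific single-cell information
#'
#' For each cell, the responses (rates over all transforms of all stimuli)
#' are discretized into `n_bins` equal-width bins spanning `[0, max]` of that
#' cell's rates, and the stimulus-specific information
#' `I(s, R) = sum_r P(r|s) log2( P(r|s) / P(r) )` is computed for each
#' stimulus with equiprobable stimuli and transforms as the trials within a
#' stimulus. A transformation-invariant, stimulus-selective cell attains the
#' ceiling `log2(N_S)` bits; a cell whose responses carry no stimulus
#' signal (including any constant responder) scores 0.
#'
#' @param rate a `rate_table` from [rates_from_spikes()].
#' @param n_bins number of rate bins (default: transforms per stimulus).
#' @return A list: `max_bits` (per-cell maximum over stimuli) and
#'   `per_stimulus` (`cell x stimulus` matrix of `I(s, R)`).
#' @export
single_cell_info <- function(rate, n_bins = dim(rate)[3]) {
  stopifnot(length(dim(rate)) == 3, n_bins >= 2)
  n_cells <- dim(rate)[1]
  n_s <- dim(rate)[2]
  n_t <- dim(rate)[3]
  per_stim <- matrix(0, n_cells, n_s)
  for (cell in seq_len(n_cells)) {
    r <- rate[cell, , , drop = TRUE]           # n_s x n_t
    r <- matrix(r, n_s, n_t)
    rmax <- max(r)
    if (rmax <= 0) next
    # bin index in 1..n_bins over equal-width bins on [0, rmax]
    bin <- pmin(floor(r / rmax * n_bins) + 1L, n_bins)
    p_r_s <- vapply(seq_len(n_s), function(s) {
      tabulate(bin[s, ], nbins = n_bins) / n_t
    }, numeric(n_bins))                         # n_bins x n_s
    p_r <- rowMeans(p_r_s)                      # equiprobable stimuli
    for (s in seq_len(n_s)) {
      nz <- p_r_s[, s] > 0
      per_stim[cell, s] <-
        sum(p_r_s[nz, s] * log2(p_r_s[nz, s] / p_r[nz]))
    }
  }
  list(max_bits = apply(per_stim, 1, max), per_stimulus = per_stim)
}

#' Multiple-cell information via Gaussian-Bayesian decoding
#'
#' Estimates how much information an ensemble of output cells carries about
#' stimulus identity. The ensemble pool holds, for each stimulus, the
#' `n_per_stimulus` cells with the most single-cell information about that
#' stimulus (at most `n_per_stimulus * N_S` cells in total). For each
#' ensemble size `k`, `n_iterations` random `k`-subsets of the pool are
#' drawn; every presentation `(s, t)` is decoded by fitting each cell's
#' response to stimulus `s'` as a Gaussian over all *other* transforms of
#' `s'` (leave-one-transform-out for `s' = s`), multiplying the per-cell
#' likelihoods with the uniform prior `P(s')`, and taking the argmax of the
#' posterior (ties broken uniformly at random). Decoded-versus-true counts
#' accumulate into a confusion table `P(s, s')` from which the mutual
#' information `I(s, s') = sum P(s,s') log2( P(s,s') / (P(s)P(s')) )` is
#' computed. The measure approaches `log2(N_S)` bits only when different
#' cells in the pool are tuned to different stimuli.
#'
#' Standard deviations are floored at `sd_floor_frac * max(rate)` so that
#' constant responders yield finite likelihoods.
#'
#' @param rate a `rate_table`.
#' @param ensemble_max largest ensemble size to evaluate.
#' @param n_iterations random cell subsets per ensemble size.
#' @param n_per_stimulus best cells kept per stimulus when forming the pool.
#' @param sd_floor_frac variance-floor fraction of the table's maximum rate.
#' @param soft logical; accumulate the full posterior instead of the hard
#'   argmax prediction.
#' @return An `info_result` list: `bits` (information at each ensemble size),
#'   `ensemble` (pool cell indices), `confusion` (the `P(s, s')` table at the
#'   largest ensemble size), `single_cell` (the [single_cell_info()] result).
#' @export
multi_cell_info <- function(rate, ensemble_max = 10, n_iterations = 100,
                            n_per_stimulus = 5, sd_floor_frac = 1e-3,
                            soft = FALSE) {
  stopifnot(length(dim(rate)) == 3)
  n_cells <- dim(rate)[1]
  n_s <- dim(rate)[2]
  n_t <- dim(rate)[3]
  if (n_t < 2) stop("need >= 2 transforms per stimulus for leave-one-out decoding")
  sci <- single_cell_info(rate)
  pool <- unique(unlist(lapply(seq_len(n_s), function(s) {
    utils::head(order(sci$per_stimulus[, s], decreasing = TRUE),
                n_per_stimulus)
  })))
  ensemble_max <- min(ensemble_max, length(pool))
  sd_floor <- max(sd_floor_frac * max(rate), .Machine$double.eps)

  # leave-one-out Gaussian fits: mean/sd of cell c for stimulus s', excluding
  # transform t when s' is the true stimulus of the decoded presentation
  fit_mean <- array(0, c(n_cells, n_s)) # full-data fits (used when s' != s)
  fit_sd <- array(0, c(n_cells, n_s))
  for (s in seq_len(n_s)) {
    m <- matrix(rate[, s, ], n_cells, n_t)
    fit_mean[, s] <- rowMeans(m)
    fit_sd[, s] <- pmax(apply(m, 1, sd), sd_floor)
  }

  decode_loglik <- function(cells, s, t) {
    # log P(r_c | s') for the presentation (s, t), per s'
    r_obs <- rate[cells, s, t]
    vapply(seq_len(n_s), function(sp) {
      if (sp == s) {
        m <- matrix(rate[cells, sp, -t], length(cells), n_t - 1)
        mu <- rowMeans(m)
        sg <- pmax(apply(m, 1, sd), sd_floor)
      } else {
        mu <- fit_mean[cells, sp]
        sg <- fit_sd[cells, sp]
      }
      sum(dnorm(r_obs, mu, sg, log = TRUE))
    }, numeric(1))
  }

  bits <- numeric(ensemble_max)
  confusion_last <- NULL
  for (k in seq_len(ensemble_max)) {
    conf <- matrix(0, n_s, n_s)
    for (it in seq_len(n_iterations)) {
      cells <- pool[sample.int(length(pool), k)]
      for (s in seq_len(n_s)) {
        for (t in seq_len(n_t)) {
          ll <- decode_loglik(cells, s, t) + log(1 / n_s)
          if (soft) {
            post <- exp(ll - max(ll))
            conf[s, ] <- conf[s, ] + post / sum(post)
          } else {
            best <- which(ll >= max(ll) - 1e-12)
            pick <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
            conf[s, pick] <- conf[s, pick] + 1
          }
        }
      }
    }
    p <- conf / sum(conf)
    ps <- rowSums(p)
    psp <- colSums(p)
    nz <- p > 0
    bits[k] <- sum(p[nz] * log2(p[nz] / outer(ps, psp)[nz]))
    if (k == ensemble_max) confusion_last <- p
  }
  structure(
    list(bits = bits, ensemble = pool, confusion = confusion_last,
         single_cell = sci),
    class = "info_result"
  )
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf(
    "<info_result: multi-cell info %.3f bits at ensemble size %d (pool of %d cells)>\n",
    x$bits[length(x$bits)], length(x$bits), length(x$ensemble)
  ))
  invisible(x)
}

#' Count synchronized spike volleys
#'
#' Lateral inhibition makes the stimulated input neurons fire in
#' near-synchronous waves ("volleys"). Spike times are clustered by gaps:
#' a new volley starts whenever the inter-spike interval across the
#' population exceeds `gap_ms`. Clusters recruiting fewer than
#' `min_frac` of the stimulated neurons are ignored.
#'
#' @param spike_times_ms spike times of the stimulated population (ms).
#' @param spike_neurons matching neuron ids (used for the recruitment check).
#' @param n_stimulated number of stimulated neurons.
#' @param window_ms observation window length (ms).
#' @param gap_ms silent gap defining a volley boundary.
#' @param min_frac minimum fraction of the population a volley must recruit.
#' @return A list: `n_volleys` and `rate_hz` (`n_volleys / window`).
#' @export
count_volleys <- function(spike_times_ms, spike_neurons, n_stimulated,
                          window_ms, gap_ms = 3, min_frac = 0.25) {
  stopifnot(length(spike_times_ms) == length(spike_neurons), window_ms > 0)
  if (length(spike_times_ms) == 0) {
    return(list(n_volleys = 0L, rate_hz = 0))
  }
  o <- order(spike_times_ms)
  tt <- spike_times_ms[o]
  nn <- spike_neurons[o]
  grp <- cumsum(c(1, diff(tt) > gap_ms))
  sizes <- vapply(split(nn, grp), function(v) length(unique(v)), integer(1))
  n_volleys <- sum(sizes >= min_frac * n_stimulated)
  list(n_volleys = as.integer(n_volleys),
       rate_hz = n_volleys / (window_ms / 1000))
}

#' Characteristic rate of responsive output cells
#'
#' Summarizes the firing-rate regime of the output layer during testing: a
#' cell is *responsive* if its peak rate across the test windows exceeds
#' `threshold_hz`, and each responsive cell contributes the rate of its best
#' (most strongly driven) window — the rate the cell attains when its
#' stimulus drives it. The mean over responsive cells is returned.
#'
#' @param rate a `rate_table`.
#' @param threshold_hz responsiveness threshold (spikes/s).
#' @return Mean driven rate (spikes/s) of responsive cells; 0 if none.
#' @export
responsive_rate <- function(rate, threshold_hz = 10) {
  peak <- apply(rate, 1, max)
  keep <- peak > threshold_hz
  if (!any(keep)) return(0)
  mean(peak[keep])
}
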